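#' Residue constant tables
#'
#' Loads the per-residue constants used by the featurizer: average residue
#' masses (Da), Kyte-Doolittle hydropathy, natural-abundance prior
#' probabilities, the ionizable-group pKa set for isoelectric-point
#' calculation, and the ambiguity-code map (B=\{D,N\}, Z=\{E,Q\}, J=\{I,L\},
#' X=all twenty, U->C, O->K). Abundance priors are renormalized to sum to 1
#' and serve as the prior for the expected-value resolution of ambiguous
#' residues.
#'
#' @param positiveResidues residues counted as positively charged
#'   (default K, R).
#' @param negativeResidues residues counted as negatively charged
#'   (default D, E).
#' @return a `ResidueTables` list with elements `mass`, `kd`, `abundance`,
#'   `pka` (data.frame), `ambiguity`, `water`, `positive`, `negative`.
#' @export
residueTables <- function(positiveResidues = c("K", "R"),
                          negativeResidues = c("D", "E")) {
  path <- system.file("extdata", "residue_tables.tsv",
                      package = "GOSlimPred", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  df <- df[match(AA20, df$residue), ]
  ab <- df$abundance / sum(df$abundance)
  pkaPath <- system.file("extdata", "pka_table.tsv",
                         package = "GOSlimPred", mustWork = TRUE)
  pka <- read.table(pkaPath, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  structure(list(
    mass = setNames(df$mass, AA20),
    kd = setNames(df$kd, AA20),
    abundance = setNames(ab, AA20),
    pka = pka,
    ambiguity = AA_AMBIG,
    water = 18.01524,
    positive = positiveResidues,
    negative = negativeResidues
  ), class = "ResidueTables")
}

## L x 20 matrix of per-position residue probabilities: one-hot for canonical
## residues; ambiguity codes get their compatible residues' abundance priors
## renormalized (the expectation rule for ambiguous characters).
residueProbMatrix <- function(seq, tables) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET_FULL))
  if (length(bad))
    stopf("illegal character '%s' at position %d", chars[bad[1]], bad[1])
  P <- matrix(0, nrow = length(chars), ncol = 20,
              dimnames = list(NULL, AA20))
  canon <- chars %in% AA20
  if (any(canon))
    P[cbind(which(canon), match(chars[canon], AA20))] <- 1
  if (!all(canon)) {
    for (i in which(!canon)) {
      comp <- tables$ambiguity[[chars[i]]]
      pr <- tables$abundance[comp]
      P[i, comp] <- pr / sum(pr)
    }
  }
  P
}

#' Amino-acid monomer frequencies (expected under ambiguity)
#'
#' Relative frequency of each of the 20 residues; an ambiguous position
#' contributes fractional counts to its compatible residues in proportion to
#' their renormalized natural-abundance priors, so the vector is the
#' statistical expected value of the composition. Always sums to 1.
#'
#' @param seq amino-acid sequence string.
#' @param tables a [residueTables] list.
#' @return named numeric vector of length 20 (order A R N D C Q E G H I L K
#'   M F P S T W Y V).
#' @export
monomerFrequencies <- function(seq, tables = residueTables()) {
  P <- residueProbMatrix(seq, tables)
  colSums(P) / nrow(P)
}

#' Amino-acid dimer (dipeptide) frequencies
#'
#' Relative frequency of every ordered residue pair among the overlapping
#' adjacent pairs (denominator: length - 1). Adjacent ambiguous positions
#' are resolved independently, each pair contributing the product of the two
#' marginal residue probabilities. For a sequence of length < 2 an all-zero
#' vector is returned with a warning.
#'
#' @inheritParams monomerFrequencies
#' @return named numeric vector of length 400 (names like "AA", "AR", ...;
#'   first residue varies slowest).
#' @export
dimerFrequencies <- function(seq, tables = residueTables()) {
  nm <- as.vector(t(outer(AA20, AA20, paste0)))  # AA, AR, ..., VV
  P <- residueProbMatrix(seq, tables)
  L <- nrow(P)
  if (L < 2) {
    warnf("sequence of length %d has no dimers; returning zeros", L)
    return(setNames(numeric(400), nm))
  }
  M <- crossprod(P[-L, , drop = FALSE], P[-1, , drop = FALSE]) / (L - 1)
  setNames(as.vector(t(M)), nm)
}

## Net charge at a given pH via Henderson-Hasselbalch over the ionizable
## groups; counts are expected counts under the ambiguity priors.
netCharge <- function(pH, counts, pka) {
  ch <- 0
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]; n <- counts[[g]]
    if (is.null(n) || n == 0) next
    if (pka$sign[i] > 0) ch <- ch + n / (1 + 10^(pH - pka$pka[i]))
    else ch <- ch - n / (1 + 10^(pka$pka[i] - pH))
  }
  ch
}

#' Physical-chemical features
#'
#' Six descriptors: sequence length (residue count), molecular weight (sum
#' of average residue masses plus one water, Da), percentage of positively
#' charged residues (K+R), percentage of negatively charged residues (D+E),
#' isoelectric point (pH of zero net charge under Henderson-Hasselbalch with
#' both termini, found by bisection to 1e-4 pH units) and GRAVY (mean
#' Kyte-Doolittle hydropathy). Ambiguous residues contribute expected values
#' throughout; for the pI the expected ionizable-group counts enter the
#' charge equation.
#'
#' @inheritParams monomerFrequencies
#' @return named numeric vector `c(length, mol_weight, pos_charge_pct,
#'   neg_charge_pct, isoelectric_point, gravy)`.
#' @export
physChemFeatures <- function(seq, tables = residueTables()) {
  P <- residueProbMatrix(seq, tables)
  L <- nrow(P)
  freq <- colSums(P) / L
  mw <- sum(P %*% tables$mass) + tables$water
  posPct <- 100 * sum(freq[tables$positive])
  negPct <- 100 * sum(freq[tables$negative])
  gravy <- sum(P %*% tables$kd) / L
  counts <- as.list(colSums(P))
  counts$Nterm <- 1; counts$Cterm <- 1
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (netCharge(mid, counts, tables$pka) > 0) lo <- mid else hi <- mid
  }
  c(length = L, mol_weight = mw, pos_charge_pct = posPct,
    neg_charge_pct = negPct, isoelectric_point = (lo + hi) / 2,
    gravy = gravy)
}

#' Secondary-structure composition features
#'
#' Frequencies of the three structural states H (alpha helix), E (beta
#' sheet), C (coil) and of their nine ordered dimers, computed exactly like
#' the residue monomer/dimer statistics. For a missing structure string the
#' configurable policy is `"zero"` (all 12 features 0) or `"error"`.
#'
#' @param ss secondary-structure string over \{H, E, C\}, or `NA`.
#' @return named numeric vector of length 3 (`ss_H`, `ss_E`, `ss_C`).
#' @export
ssFrequencies <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  validateSequence(ss, "ss", SS3)
  n <- vapply(SS3, function(s) sum(chars == s), 0)
  setNames(n / length(chars), paste0("ss_", SS3))
}

#' @rdname ssFrequencies
#' @return for the dimer form, named numeric vector of length 9
#'   (`ss_HH` ... `ss_CC`).
#' @export
ssDimerFrequencies <- function(ss) {
  nm <- paste0("ss_", as.vector(t(outer(SS3, SS3, paste0))))
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  validateSequence(ss, "ss", SS3)
  L <- length(chars)
  if (L < 2) {
    warnf("structure string of length %d has no dimers; returning zeros", L)
    return(setNames(numeric(9), nm))
  }
  pairs <- paste0(chars[-L], chars[-1])
  lv <- as.vector(t(outer(SS3, SS3, paste0)))
  setNames(as.vector(table(factor(pairs, levels = lv))) / (L - 1), nm)
}

#' Names of the 438 features in canonical order
#'
#' 6 physical-chemical, 20 monomer, 400 dimer, 3 structure, 9 structural
#' dimer features. The order is fixed and identical across runs.
#'
#' @return character vector of length 438.
#' @export
featureNames438 <- function() {
  c("length", "mol_weight", "pos_charge_pct", "neg_charge_pct",
    "isoelectric_point", "gravy",
    paste0("freq_", AA20),
    paste0("dimer_", as.vector(t(outer(AA20, AA20, paste0)))),
    paste0("ss_", SS3),
    paste0("ss_", as.vector(t(outer(SS3, SS3, paste0)))))
}

#' Block membership of the 438 features
#' @return factor of length 438 with levels `physchem`, `monomer`, `dimer`,
#'   `ss`, `ss_dimer`, parallel to [featureNames438].
#' @export
featureBlocks <- function() {
  factor(rep(c("physchem", "monomer", "dimer", "ss", "ss_dimer"),
             c(6, 20, 400, 3, 9)),
         levels = c("physchem", "monomer", "dimer", "ss", "ss_dimer"))
}

#' Featurize a ProteinSet into the 438-column feature matrix
#'
#' Concatenates, per protein, the six physical-chemical descriptors, 20
#' monomer and 400 dimer frequencies, and 3 + 9 secondary-structure
#' composition features, in the fixed order of [featureNames438].
#'
#' @param x a [ProteinSet-class]
#' @param tables a [residueTables] list.
#' @param missingSs `"zero"` (default: proteins without a structure string
#'   get 0 for the 12 structure features, recorded in the
#'   `"missingSs"` attribute) or `"error"`.
#' @return numeric matrix, proteins x 438, rownames = protein ids.
#' @export
featurize <- function(x, tables = residueTables(),
                      missingSs = c("zero", "error")) {
  missingSs <- match.arg(missingSs)
  nm <- featureNames438()
  seqs <- sequences(x); ss <- ssStrings(x)
  mat <- matrix(0, nrow = length(seqs), ncol = length(nm),
                dimnames = list(names(seqs), nm))
  for (i in seq_along(seqs)) {
    mono <- monomerFrequencies(seqs[i], tables)
    dim2 <- suppressWarnings(dimerFrequencies(seqs[i], tables))
    pc <- physChemFeatures(seqs[i], tables)
    if (is.na(ss[i])) {
      if (missingSs == "error")
        stopf("protein '%s' has no secondary-structure string", names(seqs)[i])
      s3 <- setNames(numeric(3), paste0("ss_", SS3))
      s9 <- setNames(numeric(9),
                     paste0("ss_", as.vector(t(outer(SS3, SS3, paste0)))))
    } else {
      s3 <- ssFrequencies(ss[i])
      s9 <- suppressWarnings(ssDimerFrequencies(ss[i]))
    }
    mat[i, ] <- c(pc, mono, dim2, s3, s9)
  }
  attr(mat, "missingSs") <- names(seqs)[is.na(ss)]
  mat
}

#' Fit / apply z-score normalization
#'
#' `fitZScore` computes per-feature mean and sample standard deviation on
#' the given row subset (the training portion during cross-validation, to
#' keep test information out of the fitted state); `applyZScore` centers and
#' scales any matrix with those parameters. Zero-variance features map to 0
#' and are flagged.
#'
#' @param mat feature matrix.
#' @param rows row subset to fit on (default all rows).
#' @return `fitZScore`: a [ZScoreState-class]; `applyZScore`: the
#'   transformed matrix.
#' @export
fitZScore <- function(mat, rows = seq_len(nrow(mat))) {
  sub <- mat[rows, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, sd)
  zero <- !is.finite(sdv) | sdv == 0
  new("ZScoreState", center = mu, scale = sdv, zeroVar = zero)
}

#' @rdname fitZScore
#' @param state a [ZScoreState-class] from `fitZScore`.
#' @export
applyZScore <- function(mat, state) {
  out <- sweep(mat, 2, state@center, "-")
  sc <- ifelse(state@zeroVar, 1, state@scale)
  out <- sweep(out, 2, sc, "/")
  out[, state@zeroVar] <- 0
  out
}
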