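## Chou-Fasman-style conformational propensities (helix, sheet, turn~coil).
## Used only by the stand-in predictor below.
ssPropensities <- function() {
  m <- matrix(c(
    # H      E      C
    1.42, 0.83, 0.66,  # A
    0.98, 0.93, 0.95,  # R
    0.67, 0.89, 1.56,  # N
    1.01, 0.54, 1.46,  # D
    0.70, 1.19, 1.19,  # C
    1.11, 1.10, 0.98,  # Q
    1.51, 0.37, 0.74,  # E
    0.57, 0.75, 1.56,  # G
    1.00, 0.87, 0.95,  # H
    1.08, 1.60, 0.47,  # I
    1.21, 1.30, 0.59,  # L
    1.16, 0.74, 1.01,  # K
    1.45, 1.05, 0.60,  # M
    1.13, 1.38, 0.60,  # F
    0.57, 0.55, 1.52,  # P
    0.77, 0.75, 1.43,  # S
    0.83, 1.19, 0.96,  # T
    1.08, 1.37, 0.96,  # W
    0.69, 1.47, 1.14,  # Y
    1.06, 1.70, 0.50   # V
  ), ncol = 3, byrow = TRUE, dimnames = list(AA20, SS3))
  m
}

#' Deterministic secondary-structure stand-in predictor
#'
#' Per-position conformational propensities (Chou-Fasman-style table,
#' expected values under the ambiguity priors) are smoothed with a centered
#' running mean of window 5 (truncated at the ends) and the argmax state is
#' emitted, ties broken in the fixed order H > E > C. This is a trivial,
#' deterministic stand-in so that pipelines can run without an external
#' structure predictor; it is *not* equivalent to a real secondary-structure
#' prediction method and carries no accuracy claim.
#'
#' @param seq amino-acid sequence string.
#' @param tables a [residueTables] list.
#' @param window smoothing window (odd, default 5).
#' @return an H/E/C string of the same length as `seq`.
#' @export
predictSsStub <- function(seq, tables = residueTables(), window = 5) {
  P <- residueProbMatrix(seq, tables)
  prop <- P %*% ssPropensities()     # L x 3 expected propensities
  L <- nrow(prop)
  half <- (window - 1) %/% 2
  sm <- prop
  if (L > 1) {
    cs <- rbind(0, apply(prop, 2, cumsum))
    for (i in seq_len(L)) {
      a <- max(1, i - half); b <- min(L, i + half)
      sm[i, ] <- (cs[b + 1, ] - cs[a, ]) / (b - a + 1)
    }
  }
  paste(SS3[max.col(sm, ties.method = "first")], collapse = "")
}

#' Attach secondary structure to a ProteinSet
#'
#' @param x a [ProteinSet-class]
#' @param source `"stub"` (run [predictSsStub]) or `"none"` (clear).
#' @param tables a [residueTables] list.
#' @return a [ProteinSet-class] with `ss` filled in.
#' @export
addSecondaryStructure <- function(x, source = c("stub", "none"),
                                  tables = residueTables()) {
  source <- match.arg(source)
  seqs <- sequences(x)
  ss <- if (source == "stub")
    vapply(seqs, predictSsStub, "", tables = tables)
  else rep(NA_character_, length(seqs))
  ProteinSet(seqs, ss)
}
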