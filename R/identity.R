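## Replace letters absent from BLOSUM62 rows we rely on by their nearest
## canonical residue; alignment only (featurization keeps full ambiguity).
canonicalizeForAlignment <- function(seq) {
  chartr("UOJ", "CKL", seq)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (opening 11, extension 1); identity is the number of identical aligned
#' positions divided by the alignment length *including gap columns* — the
#' stricter, argument-order-independent convention (note: Cd-Hit divides by
#' the shorter sequence length instead, so values here are systematically
#' lower or equal). Symmetric, in [0, 1].
#'
#' @param a,b amino-acid sequence strings.
#' @param gapOpening,gapExtension affine gap penalties (positive).
#' @return identity fraction in [0, 1].
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 11, gapExtension = 1) {
  if (nchar(a) == 0 || nchar(b) == 0) stopf("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    canonicalizeForAlignment(a), canonicalizeForAlignment(b),
    substitutionMatrix = blosum62(), gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

## Vectorized identity of one sequence against many (same convention).
identityAgainst <- function(query, subjects, gapOpening = 11,
                            gapExtension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(canonicalizeForAlignment(subjects)),
    canonicalizeForAlignment(query),
    substitutionMatrix = blosum62(), gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Greedy identity-based redundancy filtering
#'
#' Direct greedy incremental clustering in the style of Cd-Hit (without its
#' k-mer prefilter): sequences are sorted by length descending (ties broken
#' by id, lexicographically); each sequence joins the first existing cluster
#' whose representative it matches at identity >= `cutoff`, otherwise it
#' founds a new cluster with itself as representative. Representatives are
#' therefore the longest member of their cluster and mutually below the
#' cutoff. Output order is deterministic.
#'
#' @param x a [ProteinSet-class]
#' @param cutoff identity cutoff in (0, 1] (the study sweeps 0.3-0.8).
#' @return list with `representatives` (a [ProteinSet-class]) and
#'   `clusters` (data.frame `representative`, `member`, `identity`).
#' @export
filterByIdentity <- function(x, cutoff) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must be in (0, 1]")
  ids <- proteinIds(x)
  if (length(ids) == 0)
    return(list(representatives = x,
                clusters = data.frame(representative = character(),
                                      member = character(),
                                      identity = numeric())))
  seqs <- sequences(x)
  ord <- order(-nchar(seqs), ids)
  reps <- character()
  member <- list()
  memIdent <- list()
  for (i in ord) {
    id <- ids[i]
    if (length(reps)) {
      idents <- identityAgainst(seqs[i], seqs[reps])
      hit <- which(idents >= cutoff)
    } else hit <- integer()
    if (length(hit)) {
      r <- reps[hit[1]]
      member[[r]] <- c(member[[r]], id)
      memIdent[[r]] <- c(memIdent[[r]], idents[hit[1]])
    } else {
      reps <- c(reps, id)
      member[[id]] <- id
      memIdent[[id]] <- 1
    }
  }
  clusters <- data.frame(
    representative = rep(reps, lengths(member[reps])),
    member = unlist(member[reps], use.names = FALSE),
    identity = unlist(memIdent[reps], use.names = FALSE),
    stringsAsFactors = FALSE)
  list(representatives = x[reps], clusters = clusters)
}
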