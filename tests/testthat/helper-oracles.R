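# Independent oracles, written against the definitions rather than the
# package implementations: affine-gap alignment DPs (Gotoh), brute-force
# Ward agglomeration, a second FCBF predominance implementation, and a
# tiny path-enumeration on toy DAGs.

oracleBlosum <- local({
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

# Global (Needleman-Wunsch) score with affine gaps costing open + k * ext
# for a gap of k residues (the same convention pairwiseAlignment uses).
nwScoreOracle <- function(a, b, open = 11, ext = 1) {
  S <- oracleBlosum()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Local (Smith-Waterman) score, same gap convention, zero floor.
swScoreOracle <- function(a, b, open = 11, ext = 1) {
  S <- oracleBlosum()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-1e9, n + 1, m + 1); Y <- X
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# Brute-force Ward agglomeration via the Lance-Williams recurrence applied
# to the supplied dissimilarities (ward.D convention): at each step merge
# the pair at minimum distance, update all distances, record heights.
wardOracle <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > k) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      i <- active[ii]; j <- active[jj]
      if (D[i, j] < bd) { bd <- D[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (l in setdiff(active, c(i, j))) {
      nl <- sizes[l]
      D[i, l] <- D[l, i] <-
        ((ni + nl) * D[i, l] + (nj + nl) * D[j, l] - nl * D[i, j]) /
        (ni + nj + nl)
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
    heights <- c(heights, bd)
  }
  assign <- integer(n)
  for (c0 in seq_along(active)) assign[members[[active[c0]]]] <- c0
  list(assignment = assign, heights = heights)
}

# Second, independently coded predominance filter (full correlation matrix
# precomputed, explicit removed set).
fcbfOracle <- function(mat, y, delta = 0) {
  r <- abs(suppressWarnings(stats::cor(mat, as.numeric(y))))[, 1]
  r[!is.finite(r)] <- 0
  names(r) <- colnames(mat)
  C <- abs(suppressWarnings(stats::cor(mat)))
  C[!is.finite(C)] <- 0
  order0 <- names(sort(r, decreasing = TRUE))
  # stable tie-break by name
  order0 <- order0[order(-r[order0], order0)]
  order0 <- order0[r[order0] >= delta]
  removed <- character()
  kept <- character()
  for (f in order0) {
    if (f %in% removed) next
    kept <- c(kept, f)
    for (g in order0[match(f, order0) < seq_along(order0)]) {
      if (g %in% removed) next
      if (C[f, g] >= r[g]) removed <- c(removed, g)
    }
  }
  kept
}

# All root-directed paths between two nodes of a toy GoDag, walking child
# edges downward from `from`; used to decide reachability avoiding a set.
pathsAvoiding <- function(dag, from, to, avoid) {
  kids <- GOSlimPred:::childMap(dag)
  found <- FALSE
  recur <- function(node) {
    if (found) return()
    if (node %in% avoid) return()
    if (node == to) { found <<- TRUE; return() }
    for (c0 in kids[[node]]) recur(c0)
  }
  for (c0 in setdiff(kids[[from]], character(0))) recur(c0)
  found
}

# A small fixed DAG used across ontology tests:
#   root A; B,C children of A; D child of B and C (diamond); L child of B.
toyDiamondDag <- function(slim = c("A", "B")) {
  GoDag(terms = c("A", "B", "C", "D", "L"),
        parents = list(character(), "A", "A", c("B", "C"), "B"),
        slim = slim)
}

randomProteinSet <- function(n, len = 40, seed = 1, ss = FALSE) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(GOSlimPred:::AA20, len, TRUE), collapse = ""), "")
    names(seqs) <- sprintf("Q%03d", seq_len(n))
    s <- if (ss) vapply(nchar(seqs), function(L)
      paste(sample(c("H", "E", "C"), L, TRUE), collapse = ""), "")
    else NULL
    ProteinSet(seqs, s)
  })
}
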