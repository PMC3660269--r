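#' Absolute Pearson correlation distance between features
#'
#' d(i, j) = 1 - |pearson(f_i, f_j)|, so perfectly correlated *and*
#' perfectly anti-correlated features are both at distance 0 (they carry
#' the same information for a linear model). Zero-variance features are at
#' distance 1 to everything (logged).
#'
#' @param mat feature matrix (rows = samples, >= 2 rows).
#' @return a `dist` object over the columns, values in [0, 1].
#' @export
absCorDist <- function(mat) {
  if (nrow(mat) < 2) stopf("need at least 2 samples to correlate")
  sdv <- apply(mat, 2, sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    warnf("%d zero-variance feature(s) set to distance 1", sum(zero))
  r <- suppressWarnings(cor(mat))
  d <- 1 - abs(r)
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' Ward clustering of features
#'
#' Agglomerative clustering with the classical Ward minimum-variance update
#' (Lance-Williams recurrence) applied directly to the supplied
#' dissimilarities — the historical `hclust(method = "ward")` behaviour, now
#' `"ward.D"`; the distances are deliberately *not* squared first since the
#' absolute-correlation distance is not Euclidean. `"ward.D2"` (squaring
#' internally) is selectable. The tree is cut to exactly `k` clusters.
#'
#' @param d a `dist` over features, as from [absCorDist].
#' @param k number of clusters (default 15, the grouping used for the
#'   per-cluster predictability analysis).
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return a [FeatureClustering-class]
#' @export
wardClusterFeatures <- function(d, k = 15, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  n <- attr(d, "Size")
  if (k > n) stopf("k = %d exceeds the %d features", k, n)
  hc <- hclust(d, method = method)
  assign <- cutree(hc, k = k)
  new("FeatureClustering", k = k, assignment = assign,
      linkage = list(merge = hc$merge, height = hc$height,
                     labels = hc$labels, method = method))
}

#' Correlation-based feature selection (FCBF-style)
#'
#' Relevance/redundancy filter in the spirit of the Fast Correlation-Based
#' Filter, with symmetrical uncertainty replaced by the absolute Pearson
#' correlation: relevance of feature i is c_iy = |cor(f_i, y)| (point-
#' biserial via 0/1 coding of y), redundancy between features is
#' c_ij = |cor(f_i, f_j)|. Features with c_iy < `delta` are dropped; the
#' remainder are ranked by decreasing c_iy (ties by name) and scanned
#' top-down: each kept feature removes every lower-ranked feature j with
#' c_ij >= c_jy (the predominance condition).
#'
#' @param mat feature matrix.
#' @param y binary label vector (0/1 or logical), both classes present.
#' @param delta relevance threshold in [0, 1] (default 0: rank-based
#'   predominance does the pruning).
#' @return list with `selected` (feature names in rank order), `relevance`
#'   (named c_iy for all features), `removed` (data.frame `feature`,
#'   `removedBy`, `cij`; `removedBy == "<delta>"` for threshold drops).
#' @export
fcbfSelect <- function(mat, y, delta = 0) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("y must contain both classes")
  ciy <- abs(suppressWarnings(cor(mat, y)))[, 1]
  ciy[!is.finite(ciy)] <- 0
  names(ciy) <- colnames(mat)
  below <- names(ciy)[ciy < delta]
  cand <- setdiff(names(ciy), below)
  cand <- cand[order(-ciy[cand], cand)]
  removedBy <- setNames(rep("<delta>", length(below)), below)
  cij <- setNames(rep(NA_real_, length(below)), below)
  keep <- character()
  while (length(cand)) {
    fi <- cand[1]
    keep <- c(keep, fi)
    cand <- cand[-1]
    if (length(cand)) {
      rr <- abs(suppressWarnings(cor(mat[, cand, drop = FALSE],
                                     mat[, fi])))[, 1]
      rr[!is.finite(rr)] <- 0
      drop <- cand[rr >= ciy[cand]]
      if (length(drop)) {
        removedBy[drop] <- fi
        cij[drop] <- rr[match(drop, cand)]
        cand <- setdiff(cand, drop)
      }
    }
  }
  removed <- data.frame(feature = names(removedBy),
                        removedBy = unname(removedBy),
                        cij = unname(cij[names(removedBy)]),
                        stringsAsFactors = FALSE)
  list(selected = keep, relevance = ciy, removed = removed)
}
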