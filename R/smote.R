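#' SMOTE: synthetic minority oversampling
#'
#' Generates `ceil(amount/100 * n)` synthetic minority samples. Each one is
#' built by picking a minority sample x uniformly, picking one of its k
#' nearest minority neighbours z (Euclidean distance in the given — already
#' normalized — feature space) and emitting x + u (z - x) with
#' u ~ Uniform(0, 1), so every synthetic point lies on a segment between two
#' minority points (hence inside their convex hull).
#'
#' @param minority numeric matrix of minority-class samples (rows).
#' @param amount oversampling percentage (100 doubles the class).
#' @param k neighbour count (default 5, the original SMOTE convention);
#'   lowered to n - 1 with a warning when the class is smaller.
#' @param seed optional seed for reproducibility (caller's RNG untouched).
#' @return matrix of synthetic samples (possibly 0 rows).
#' @export
smote <- function(minority, amount = 100, k = 5, seed = NULL) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  nSyn <- ceiling(amount / 100 * n)
  if (nSyn == 0)
    return(minority[integer(), , drop = FALSE])
  if (n == 1) {
    warnf("singleton minority class: duplicating the sample")
    return(minority[rep(1, nSyn), , drop = FALSE])
  }
  if (k >= n) {
    warnf("k = %d >= minority size %d; using k = %d", k, n, n - 1)
    k <- n - 1
  }
  d2 <- as.matrix(stats::dist(minority))^2
  diag(d2) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n),
                              function(i) order(d2[i, ])[seq_len(k)]))
  withLocalSeed(seed, {
    base <- sample.int(n, nSyn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, nSyn, replace = TRUE))]
    u <- runif(nSyn)
    minority[base, , drop = FALSE] +
      u * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
  })
}
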