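#' Train a Gaussian-kernel SVM
#'
#' Thin wrapper around `kernlab::ksvm` (C-SVC) with the radial basis kernel
#' parameterized by the kernel *width* sigma:
#' K(x, z) = exp(-||x - z||^2 / (2 sigma^2)). Features are assumed already
#' normalized; no internal scaling is applied.
#'
#' @param X numeric matrix (rows = samples).
#' @param y binary labels (0/1, logical or factor with two levels).
#' @param sigma kernel width (> 0).
#' @param C soft-margin penalty (> 0).
#' @return a `GoSvm` object usable with [predictSvm].
#' @export
trainSvm <- function(X, y, sigma, C) {
  if (sigma <= 0 || C <= 0) stopf("sigma and C must be positive")
  yf <- factor(as.integer(as.numeric(y) > 0), levels = c(0, 1))
  if (nlevels(droplevels(yf)) < 2) stopf("both classes must be present")
  kpar <- list(sigma = 1 / (2 * sigma^2))  # kernlab uses exp(-s||x-z||^2)
  fit <- tryCatch(
    kernlab::ksvm(as.matrix(X), yf, type = "C-svc", kernel = "rbfdot",
                  kpar = kpar, C = C, scaled = FALSE),
    error = function(e) stopf("SVM training failed (sigma=%g, C=%g): %s",
                              sigma, C, conditionMessage(e)))
  structure(list(fit = fit, sigma = sigma, C = C,
                 features = colnames(X)), class = "GoSvm")
}

#' @rdname trainSvm
#' @param model a `GoSvm` from [trainSvm].
#' @param newX matrix of samples to classify.
#' @return integer vector of 0/1 predictions.
#' @export
predictSvm <- function(model, newX) {
  p <- kernlab::predict(model$fit, as.matrix(newX), type = "response")
  as.integer(as.character(p))
}

#' Median-distance heuristic for the kernel width
#'
#' sigma = median pairwise Euclidean distance on (a subsample of) the rows;
#' a standard default when the width is not tuned.
#'
#' @param X feature matrix.
#' @param maxRows subsample cap for the distance computation.
#' @return positive scalar.
#' @export
sigmaHeuristic <- function(X, maxRows = 200) {
  n <- nrow(X)
  idx <- if (n > maxRows) round(seq(1, n, length.out = maxRows)) else seq_len(n)
  d <- as.vector(stats::dist(X[idx, , drop = FALSE]))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Confusion-matrix based fold metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) (0 when the
#' denominator is 0) and their geometric mean, the imbalance-robust summary
#' used throughout.
#'
#' @param truth,pred 0/1 vectors.
#' @param fold fold index to record.
#' @return one-row data.frame `fold, TP, TN, FP, FN, sens, spec, gmean`.
#' @export
foldMetrics <- function(truth, pred, fold = NA_integer_) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  TP <- sum(truth == 1 & pred == 1); TN <- sum(truth == 0 & pred == 0)
  FP <- sum(truth == 0 & pred == 1); FN <- sum(truth == 1 & pred == 0)
  sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  spec <- if (TN + FP == 0) 0 else TN / (TN + FP)
  data.frame(fold = fold, TP = TP, TN = TN, FP = FP, FN = FN,
             sens = sens, spec = spec, gmean = gmean(sens, spec))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `nFolds` folds preserving the class ratio:
#' positives and negatives are shuffled separately (under `seed`) and dealt
#' round-robin.
#'
#' @param y 0/1 labels.
#' @param nFolds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..nFolds.
#' @export
stratifiedFolds <- function(y, nFolds = 5, seed = NULL) {
  y <- as.integer(as.numeric(y) > 0)
  if (min(sum(y == 1), sum(y == 0)) < nFolds)
    stopf("fewer samples in a class (%d) than folds (%d)",
          min(sum(y == 1), sum(y == 0)), nFolds)
  folds <- integer(length(y))
  withLocalSeed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}
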