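#' Settings for one-vs-all term evaluation
#'
#' @param nFolds outer cross-validation folds (default 5: 80% train / 20%
#'   test per repetition).
#' @param tune tune (sigma, C) by PSO over an inner CV (default TRUE); when
#'   FALSE, `fixedSigma` (default: median-distance heuristic) and `fixedC`
#'   are used.
#' @param pso a [psoSettings] list for the tuner.
#' @param innerFolds folds of the inner CV the tuner maximizes (default 3).
#' @param fcbf run [fcbfSelect] on the training portion of each fold.
#' @param delta FCBF relevance threshold.
#' @param smote balance the training minority class to parity by SMOTE.
#' @param smoteK SMOTE neighbour count (default 5).
#' @param fixedSigma,fixedC hyperparameters when `tune = FALSE`
#'   (`fixedSigma = NULL` uses [sigmaHeuristic]).
#' @param seed seed controlling folds, SMOTE and PSO streams.
#' @return an `EvalSettings` list.
#' @export
evalSettings <- function(nFolds = 5, tune = TRUE, pso = psoSettings(),
                         innerFolds = 3, fcbf = FALSE, delta = 0,
                         smote = TRUE, smoteK = 5,
                         fixedSigma = NULL, fixedC = 1, seed = 1) {
  structure(list(nFolds = nFolds, tune = tune, pso = pso,
                 innerFolds = innerFolds, fcbf = fcbf, delta = delta,
                 smote = smote, smoteK = smoteK, fixedSigma = fixedSigma,
                 fixedC = fixedC, seed = seed),
            class = "EvalSettings")
}

## Mean CV G-mean of an SVM with the given hyperparameters; used as the
## tuning objective on the (already balanced) training portion.
innerCvGmean <- function(X, y, sigma, C, nFolds, seed) {
  folds <- stratifiedFolds(y, nFolds, seed)
  gs <- vapply(seq_len(nFolds), function(f) {
    tr <- folds != f
    m <- trainSvm(X[tr, , drop = FALSE], y[tr], sigma, C)
    foldMetrics(y[!tr], predictSvm(m, X[!tr, , drop = FALSE]))$gmean
  }, 0)
  mean(gs)
}

#' Evaluate one slim category under stratified cross-validation
#'
#' One-vs-all protocol for a single binary problem: stratified `nFolds`-fold
#' split; per fold the z-score normalization is fitted on the training
#' portion only and applied to both portions, FCBF selection (optional) runs
#' on the training portion only, SMOTE brings the training minority class to
#' parity with the majority, hyperparameters are PSO-tuned against an inner
#' CV on the balanced training set (or fixed), the SVM is trained and the
#' held-out portion scored. No test-fold information reaches any fitting
#' step.
#'
#' @param X raw (unnormalized) feature matrix with protein rownames.
#' @param y 0/1 labels parallel to rows.
#' @param settings an [evalSettings] list.
#' @return list with `metrics` (data.frame of per-fold confusion counts,
#'   sensitivity, specificity, G-mean), `predictions` (named 0/1 vector,
#'   each protein scored by the fold that held it out), `folds` (the fold
#'   assignment), `hyper` (per-fold sigma/C), `selected` (per-fold feature
#'   list when `fcbf`).
#' @export
evaluateTerm <- function(X, y, settings = evalSettings()) {
  y <- as.integer(as.numeric(y) > 0)
  folds <- stratifiedFolds(y, settings$nFolds, settings$seed)
  preds <- setNames(integer(length(y)), rownames(X))
  metrics <- NULL
  hyper <- NULL
  selected <- vector("list", settings$nFolds)
  for (f in seq_len(settings$nFolds)) {
    tr <- which(folds != f); te <- which(folds == f)
    zs <- fitZScore(X, tr)
    Xtr <- applyZScore(X[tr, , drop = FALSE], zs)
    Xte <- applyZScore(X[te, , drop = FALSE], zs)
    ytr <- y[tr]
    if (settings$fcbf) {
      sel <- fcbfSelect(Xtr, ytr, settings$delta)$selected
      if (length(sel) == 0) {
        rel <- fcbfSelect(Xtr, ytr, 0)$relevance
        sel <- names(which.max(rel))
      }
      selected[[f]] <- sel
      Xtr <- Xtr[, sel, drop = FALSE]
      Xte <- Xte[, sel, drop = FALSE]
    }
    if (settings$smote) {
      nPos <- sum(ytr == 1); nNeg <- sum(ytr == 0)
      minCls <- if (nPos <= nNeg) 1L else 0L
      nMin <- min(nPos, nNeg); nMaj <- max(nPos, nNeg)
      if (nMaj > nMin) {
        syn <- smote(Xtr[ytr == minCls, , drop = FALSE],
                     amount = 100 * (nMaj - nMin) / nMin,
                     k = min(settings$smoteK, nMin - 1),
                     seed = childSeed(settings$seed, f))
        Xtr <- rbind(Xtr, syn)
        ytr <- c(ytr, rep(minCls, nrow(syn)))
      }
    }
    if (settings$tune) {
      obj <- function(sigma, C)
        innerCvGmean(Xtr, ytr, sigma, C, settings$innerFolds,
                     childSeed(settings$seed, 100 + f))
      best <- psoTune(obj, settings$pso,
                      seed = childSeed(settings$seed, 200 + f))
      sigma <- best$sigma; C <- best$C
    } else {
      sigma <- if (is.null(settings$fixedSigma)) sigmaHeuristic(Xtr)
               else settings$fixedSigma
      C <- settings$fixedC
    }
    model <- trainSvm(Xtr, ytr, sigma, C)
    pte <- predictSvm(model, Xte)
    preds[te] <- pte
    metrics <- rbind(metrics, foldMetrics(y[te], pte, f))
    hyper <- rbind(hyper, data.frame(fold = f, sigma = sigma, C = C))
  }
  list(metrics = metrics, predictions = preds, folds = folds,
       hyper = hyper, selected = selected)
}

#' Evaluate every term against every feature cluster
#'
#' Runs [evaluateTerm] once per (slim term, feature cluster) restricted to
#' that cluster's columns, plus a `"full"` column using FCBF selection over
#' the whole feature set. The returned ordering sorts terms by mean G-mean
#' descending and feature groups by their column mean descending, putting
#' the best-predicted categories on top and the most discriminant groups
#' first.
#'
#' @param X raw feature matrix (proteins x features).
#' @param labels a [LabelMatrix-class] aligned with `X`'s rows.
#' @param clustering a [FeatureClustering-class] covering `colnames(X)`, or
#'   NULL to run only the `"full"` column.
#' @param terms term subset (default: all label columns).
#' @param settings an [evalSettings] list (the `fcbf` flag is forced on for
#'   the `"full"` group and off inside single clusters).
#' @param includeFull add the `"full"` all-features-with-FCBF column
#'   (default TRUE).
#' @return list with `results` (long data.frame: term, group, fold, TP, TN,
#'   FP, FN, sens, spec, gmean), `summary` (term x group mean G-mean
#'   matrix, rows/columns in the sorted order), `predictions` (proteins x
#'   terms 0/1 matrix from the `"full"` runs, NULL if absent).
#' @export
runGrid <- function(X, labels, clustering = NULL, terms = NULL,
                    settings = evalSettings(), includeFull = TRUE) {
  m <- labelValues(labels)
  if (is.null(terms)) terms <- colnames(m)
  stopifnot(all(rownames(m) == rownames(X)))
  groups <- list()
  if (!is.null(clustering)) {
    a <- clusterAssignment(clustering)
    stopifnot(all(names(a) %in% colnames(X)))
    for (g in sort(unique(a)))
      groups[[as.character(g)]] <- names(a)[a == g]
  }
  res <- NULL
  preds <- NULL
  for (tm in terms) {
    y <- m[, tm]
    for (g in names(groups)) {
      s <- settings; s$fcbf <- FALSE
      ev <- evaluateTerm(X[, groups[[g]], drop = FALSE], y, s)
      res <- rbind(res, cbind(term = tm, group = g, ev$metrics))
    }
    if (includeFull) {
      s <- settings; s$fcbf <- TRUE
      ev <- evaluateTerm(X, y, s)
      res <- rbind(res, cbind(term = tm, group = "full", ev$metrics))
      preds <- cbind(preds, ev$predictions)
      colnames(preds)[ncol(preds)] <- tm
    }
  }
  agg <- stats::aggregate(gmean ~ term + group, data = res, FUN = mean)
  sm <- stats::xtabs(gmean ~ term + group, data = agg)
  sm <- matrix(sm, nrow = nrow(sm), dimnames = dimnames(sm))
  rowOrd <- order(-rowMeans(sm), rownames(sm))
  colOrd <- order(-colMeans(sm), colnames(sm))
  sm <- sm[rowOrd, colOrd, drop = FALSE]
  list(results = res, summary = sm, predictions = preds)
}

#' Accuracy of propagated predictions per term
#'
#' Predictions are propagated up the slim DAG with
#' [propagatePredictions]; the reference labels are rebuilt the same way so
#' that every category includes all its descendants (the asterisk marking
#' no longer applies). Per-term accuracy (TP+TN)/N, sensitivity and
#' specificity are reported.
#'
#' @param pred a [LabelMatrix-class] of raw per-term predictions.
#' @param truth a [LabelMatrix-class] of unpropagated reference labels on
#'   the same proteins/terms.
#' @param dag the [GoDag-class]
#' @return data.frame `term, accuracy, sens, spec, gmean`.
#' @export
evaluatePropagated <- function(pred, truth, dag) {
  pp <- labelValues(propagatePredictions(pred, dag))
  tt <- labelValues(propagatePredictions(truth, dag))
  stopifnot(all(dim(pp) == dim(tt)), all(colnames(pp) == colnames(tt)))
  out <- NULL
  for (tm in colnames(pp)) {
    fm <- foldMetrics(tt[, tm], pp[, tm])
    out <- rbind(out, data.frame(term = tm,
                                 accuracy = (fm$TP + fm$TN) / nrow(pp),
                                 sens = fm$sens, spec = fm$spec,
                                 gmean = fm$gmean))
  }
  out
}
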