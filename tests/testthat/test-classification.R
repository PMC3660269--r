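test_that("G-mean identities hold", {
  expect_equal(GOSlimPred:::gmean(1, 1), 1)
  expect_equal(GOSlimPred:::gmean(0, 0.9), 0)
  expect_equal(GOSlimPred:::gmean(0.8, 0.5), 0.6324555, tolerance = 1e-6)
  fm <- foldMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(fm$sens, fm$spec, fm$gmean), c(1, 1, 1))
  fm0 <- foldMetrics(c(0, 0), c(0, 1))     # no positives in truth
  expect_equal(fm0$sens, 0)
  expect_equal(fm0$spec, 0.5)
})

test_that("SMOTE interpolates between minority neighbours", {
  minority <- rbind(c(0, 0), c(1, 1))
  syn <- smote(minority, amount = 100, k = 1, seed = 1)
  expect_equal(nrow(syn), 2)
  # convexity forces equal coordinates on the segment (0,0)-(1,1)
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)
  expect_true(all(syn >= 0 & syn <= 1))

  expect_equal(nrow(smote(minority, amount = 0, k = 1)), 0)
  expect_warning(syn1 <- smote(minority[1, , drop = FALSE], 100, k = 1),
                 "singleton")
  expect_equal(nrow(syn1), 1)
  expect_warning(smote(minority, 100, k = 5, seed = 1), "k = 5")
  # reproducibility under seed
  expect_identical(smote(minority, 300, k = 1, seed = 42),
                   smote(minority, 300, k = 1, seed = 42))
})

test_that("SMOTE output stays on segments between minority points
           (convex-hull oracle)", {
  pts <- withr::with_seed(6, {
    th <- runif(50, 0, 2 * pi); r <- sqrt(runif(50))
    cbind(r * cos(th), r * sin(th))
  })
  syn <- smote(pts, amount = 100, k = 5, seed = 7)
  onSegment <- function(s) {
    for (i in 1:49) for (j in (i + 1):50) {
      v <- pts[j, ] - pts[i, ]; w <- s - pts[i, ]
      u <- sum(w * v) / sum(v * v)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((w - u * v)^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, onSegment)))
})

test_that("the Gaussian SVM separates easy geometry and fits XOR", {
  withr::with_seed(12, {
    X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
    y <- rep(c(0, 1), each = 30)
    m <- trainSvm(X, y, sigma = 1, C = 10)
    expect_equal(predictSvm(m, X), y)
  })
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- c(0, 0, 1, 1)
  mx <- trainSvm(Xx, yx, sigma = 0.3, C = 100)
  expect_equal(predictSvm(mx, Xx), yx)

  # consistent feature permutation leaves predictions unchanged
  withr::with_seed(13, {
    X <- matrix(rnorm(200), 50, 4); y <- rbinom(50, 1, 0.5)
    perm <- sample(4)
    m1 <- trainSvm(X, y, 1, 1)
    m2 <- trainSvm(X[, perm], y, 1, 1)
    expect_equal(predictSvm(m1, X), predictSvm(m2, X[, perm]))
  })
  expect_error(trainSvm(matrix(1, 4, 2), rep(1, 4), 1, 1), "both classes")
})

test_that("PSO recovers a known analytic optimum and is seed-deterministic", {
  obj <- function(sigma, C) -(log10(sigma) - 0)^2 - (log10(C) - 1)^2
  out <- psoTune(obj, psoSettings(swarm = 15, iterations = 30), seed = 4)
  expect_lt(abs(log10(out$sigma) - 0), 0.05)
  expect_lt(abs(log10(out$C) - 1), 0.05)

  out2 <- psoTune(obj, psoSettings(swarm = 15, iterations = 30), seed = 4)
  expect_identical(out, out2)

  out0 <- psoTune(obj, psoSettings(swarm = 10, iterations = 0), seed = 5)
  expect_equal(out0$evaluations, 10)    # best of the initial swarm only
  # non-finite objectives are tolerated
  bad <- function(sigma, C) if (C > 1) NaN else log10(sigma)
  expect_no_error(psoTune(bad, psoSettings(swarm = 5, iterations = 3),
                          seed = 6))
})

test_that("stratified folds preserve both classes in every fold", {
  y <- c(rep(1, 12), rep(0, 48))
  f <- stratifiedFolds(y, 5, seed = 3)
  for (k in 1:5) {
    expect_gte(sum(y == 1 & f == k), 2)
    expect_gte(sum(y == 0 & f == k), 9)
  }
  expect_error(stratifiedFolds(c(1, 1, 0, 0), 5), "folds")
  expect_identical(stratifiedFolds(y, 5, seed = 3),
                   stratifiedFolds(y, 5, seed = 3))
})

test_that("evaluateTerm recovers a strong planted signal and stays at
           chance on noise (leakage guard)", {
  withr::with_seed(14, {
    n <- 120
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("P%03d", 1:n), paste0("f", 1:10)))
    y <- rep(c(0, 1), each = n / 2)
    Xs <- X
    Xs[, 1] <- Xs[, 1] + 3 * y                  # planted signal
    evS <- evaluateTerm(Xs, y, evalSettings(tune = FALSE, fcbf = TRUE,
                                            seed = 2))
    expect_gte(mean(evS$metrics$gmean), 0.8)
    expect_equal(nrow(evS$metrics), 5)
    # pure noise: any leak of test-fold information into normalization,
    # selection, SMOTE or tuning would lift this off chance
    evN <- evaluateTerm(X, y, evalSettings(tune = FALSE, fcbf = TRUE,
                                           seed = 2))
    expect_lt(abs(mean(evN$metrics$gmean) - 0.5), 0.15)
    # every protein is scored exactly once, by the fold holding it out
    expect_equal(sort(names(evS$predictions)), sort(rownames(X)))
  })
})

test_that("runGrid produces the shape contract and a deterministic
           ordering", {
  cfg <- generatorConfig(seed = 31, depth = 3, branching = 2,
                         slimFraction = 0.5,
                         classes = list(
                           list(n = 40, signal = list(residues = c("K", "R"),
                                                      fold = 2.5)),
                           list(n = 40)),
                         background = 40,
                         lengthMeanLog = log(80), lengthSdLog = 0.2)
  b <- generateSequences(cfg)
  X <- featurize(b$proteins)
  lm <- filterMinSize(buildLabelMatrix(b$annotations, b$dag,
                                       proteins = proteinIds(b$proteins)),
                      30)
  fn <- featureNames438()
  assign <- setNames(ifelse(featureBlocks() %in% c("ss", "ss_dimer"),
                            2L, 1L), fn)
  cl <- new("FeatureClustering", k = 2, assignment = assign,
            linkage = list())
  g <- runGrid(X, lm, cl, settings = evalSettings(tune = FALSE, seed = 5),
               includeFull = FALSE)
  expect_equal(nrow(g$results), ncol(labelValues(lm)) * 2 * 5)
  expect_equal(dim(g$summary), c(ncol(labelValues(lm)), 2L))
  # ordering: row/column means non-increasing
  expect_true(all(diff(rowMeans(g$summary)) <= 1e-12))
  expect_true(all(diff(colMeans(g$summary)) <= 1e-12))
})

test_that("propagated-prediction accuracy follows the toy confusion
           oracles", {
  dag <- GoDag(c("A", "B"), list(character(), "A"), slim = c("A", "B"))
  ids <- sprintf("P%02d", 1:10)
  truth <- LabelMatrix(matrix(c(rep(0L, 10), rep(c(1L, 0L), each = 5)),
                              10, 2, dimnames = list(ids, c("A", "B"))))
  # child B perfectly predicted, parent A never predicted directly
  pred <- LabelMatrix(matrix(c(rep(0L, 10), rep(c(1L, 0L), each = 5)),
                             10, 2, dimnames = list(ids, c("A", "B"))))
  out <- evaluatePropagated(pred, truth, dag)
  expect_equal(out$accuracy[out$term == "A"], 1)   # inherits B's positives
  expect_equal(out$accuracy[out$term == "B"], 1)

  # no predictions at all: accuracy equals the prevalence of negatives
  none <- LabelMatrix(matrix(0L, 10, 2, dimnames = list(ids, c("A", "B"))))
  out0 <- evaluatePropagated(none, truth, dag)
  expect_equal(out0$accuracy[out0$term == "A"], 0.5)

  # propagation can only add positives: parent sensitivity never drops
  withr::with_seed(15, {
    for (i in 1:5) {
      p <- matrix(rbinom(20, 1, 0.4), 10, 2,
                  dimnames = list(ids, c("A", "B")))
      sensBefore <- foldMetrics(labelValues(propagatePredictions(truth, dag))[, "A"],
                                p[, "A"])$sens
      pProp <- labelValues(propagatePredictions(LabelMatrix(p), dag))
      sensAfter <- foldMetrics(labelValues(propagatePredictions(truth, dag))[, "A"],
                               pProp[, "A"])$sens
      expect_gte(sensAfter, sensBefore)
    }
  })
})
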