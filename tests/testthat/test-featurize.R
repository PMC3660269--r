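tabs <- residueTables()

test_that("monomer frequencies count residues and resolve ambiguity by
           renormalized priors", {
  f <- monomerFrequencies("AAC", tabs)
  expect_equal(unname(f["A"]), 2 / 3)
  expect_equal(unname(f["C"]), 1 / 3)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # B = {D, N} with renormalized abundance priors, closed form
  pD <- tabs$abundance[["D"]]; pN <- tabs$abundance[["N"]]
  f <- monomerFrequencies("B", tabs)
  expect_equal(unname(f["D"]), pD / (pD + pN), tolerance = 1e-12)
  expect_equal(unname(f["N"]), pN / (pD + pN), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  expect_error(monomerFrequencies("AC1E", tabs), "position 3")
})

test_that("X resolves to the abundance prior, matching a sampling oracle", {
  f <- monomerFrequencies(strrep("X", 10), tabs)
  expect_equal(unname(f), unname(tabs$abundance), tolerance = 1e-12)
  # Monte-Carlo resolution of X: empirical frequency over 1e5 draws must
  # agree within 3 standard errors
  draws <- withr::with_seed(7, sample(names(tabs$abundance), 1e5, TRUE,
                                      tabs$abundance))
  emp <- table(factor(draws, names(tabs$abundance))) / 1e5
  se <- sqrt(tabs$abundance * (1 - tabs$abundance) / 1e5)
  expect_true(all(abs(as.vector(emp) - f) <= 3 * se + 1e-12))
})

test_that("dimer frequencies use overlapping pairs and independent
           ambiguity resolution", {
  f <- dimerFrequencies("AAC", tabs)
  expect_equal(unname(f["AA"]), 0.5)
  expect_equal(unname(f["AC"]), 0.5)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # "ABA": B resolved into D/N with renormalized priors p', two dimers each
  pD <- tabs$abundance[["D"]]; pN <- tabs$abundance[["N"]]
  pDr <- pD / (pD + pN); pNr <- pN / (pD + pN)
  f <- dimerFrequencies("ABA", tabs)
  expect_equal(unname(f[c("AD", "AN", "DA", "NA")]),
               c(pDr, pNr, pDr, pNr) / 2, tolerance = 1e-12)

  expect_warning(f1 <- dimerFrequencies("A", tabs), "no dimers")
  expect_equal(sum(f1), 0)
})

test_that("dimer expectation equals exhaustive enumeration of ambiguity
           resolutions", {
  seq <- "ABCBAD"   # two Bs -> 4 resolutions
  pD <- tabs$abundance[["D"]]; pN <- tabs$abundance[["N"]]
  pr <- c(D = pD / (pD + pN), N = pN / (pD + pN))
  expected <- numeric(400)
  names(expected) <- names(dimerFrequencies("AA", tabs))
  for (r1 in c("D", "N")) for (r2 in c("D", "N")) {
    resolved <- chartr("B", "?", seq)
    resolved <- sub("?", r1, resolved, fixed = TRUE)
    resolved <- sub("?", r2, resolved, fixed = TRUE)
    expected <- expected + pr[[r1]] * pr[[r2]] * dimerFrequencies(resolved, tabs)
  }
  expect_equal(dimerFrequencies(seq, tabs), expected, tolerance = 1e-12)

  long <- withr::with_seed(5, paste(sample(GOSlimPred:::AA20, 200, TRUE),
                                    collapse = ""))
  expect_equal(sum(dimerFrequencies(long, tabs)), 1, tolerance = 1e-9)
})

test_that("physical-chemical descriptors match their definitions", {
  pc <- physChemFeatures("AAAA", tabs)
  expect_equal(unname(pc["gravy"]), 1.8)        # Kyte-Doolittle A = 1.8
  expect_equal(unname(pc["length"]), 4)
  expect_equal(unname(pc["mol_weight"]),
               4 * tabs$mass[["A"]] + tabs$water, tolerance = 1e-9)

  pc <- physChemFeatures("ACDE", tabs)
  expect_equal(unname(pc["neg_charge_pct"]), 50)
  expect_equal(unname(pc["pos_charge_pct"]), 0)

  # acidic vs basic ordering of the isoelectric point
  piDD <- physChemFeatures("DD", tabs)[["isoelectric_point"]]
  piKK <- physChemFeatures("KK", tabs)[["isoelectric_point"]]
  expect_lt(piDD, 7); expect_gt(piKK, 7)

  # independent bisection oracle on the same charge model
  chargeAt <- function(pH, counts) {
    tot <- 0
    for (i in seq_len(nrow(tabs$pka))) {
      g <- tabs$pka$group[i]
      n <- if (g %in% c("Nterm", "Cterm")) 1 else counts[[g]]
      if (is.null(n) || is.na(n) || n == 0) next
      tot <- tot + if (tabs$pka$sign[i] > 0) n / (1 + 10^(pH - tabs$pka$pka[i]))
                   else -n / (1 + 10^(tabs$pka$pka[i] - pH))
    }
    tot
  }
  for (seq in c("DD", "KK", "ACDEFGHIKL")) {
    counts <- as.list(table(strsplit(seq, "")[[1]]))
    pi0 <- stats::uniroot(chargeAt, c(0, 14), counts = counts,
                          tol = 1e-6)$root
    expect_equal(physChemFeatures(seq, tabs)[["isoelectric_point"]], pi0,
                 tolerance = 1e-3, label = seq)
  }
})

test_that("molecular weight is additive up to one water", {
  s1 <- "ACDEF"; s2 <- "KLMNP"
  mw <- function(s) physChemFeatures(s, tabs)[["mol_weight"]]
  expect_equal(mw(paste0(s1, s2)), mw(s1) + mw(s2) - tabs$water,
               tolerance = 1e-9)
})

test_that("secondary-structure composition features behave like the
           residue statistics", {
  f <- ssFrequencies("HHCC")
  expect_equal(unname(f), c(0.5, 0, 0.5))
  d <- ssDimerFrequencies("HHCC")
  expect_equal(unname(d[c("ss_HH", "ss_HC", "ss_CC")]), rep(1 / 3, 3))
  expect_warning(d1 <- ssDimerFrequencies("H"), "no dimers")
  expect_equal(sum(d1), 0)

  # law of large numbers on a uniform random string
  long <- withr::with_seed(11, paste(sample(c("H", "E", "C"), 3e4, TRUE),
                                     collapse = ""))
  expect_equal(unname(ssFrequencies(long)), rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(unname(ssDimerFrequencies(long)), rep(1 / 9, 9),
               tolerance = 0.01)
})

test_that("featurize emits the stable 438-column layout", {
  p <- randomProteinSet(3, len = 50, seed = 21, ss = TRUE)
  X <- featurize(p, tabs)
  expect_equal(dim(X), c(3L, 438L))
  expect_identical(colnames(X), featureNames438())
  expect_identical(featureNames438(), featureNames438())  # deterministic
  mono <- X[, featureBlocks() == "monomer", drop = FALSE]
  expect_equal(unname(rowSums(mono)), rep(1, 3), tolerance = 1e-9)
  dimer <- X[, featureBlocks() == "dimer", drop = FALSE]
  expect_equal(unname(rowSums(dimer)), rep(1, 3), tolerance = 1e-9)
})

test_that("permuting a sequence fixes monomer but not necessarily dimer
           features", {
  s <- "ACDEFGHIKLACDEFGHIKL"
  sp <- withr::with_seed(3, paste(sample(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(monomerFrequencies(s, tabs), monomerFrequencies(sp, tabs))
  expect_equal(physChemFeatures(s, tabs)[["mol_weight"]],
               physChemFeatures(sp, tabs)[["mol_weight"]])
})

test_that("missing secondary structure follows the configured policy", {
  p <- ProteinSet(c(P1 = "ACDEFGHIKL"))
  X <- featurize(p, tabs)
  expect_equal(unname(X[1, featureBlocks() %in% c("ss", "ss_dimer")]),
               numeric(12))
  expect_equal(attr(X, "missingSs"), "P1")
  expect_error(featurize(p, tabs, missingSs = "error"), "P1")
})

test_that("z-score fits on the stated rows only and flags zero variance", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(m) <- paste0("P", 1:3)
  st <- fitZScore(m)
  z <- applyZScore(m, st)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))   # sample sd
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_true(st@zeroVar[["b"]])

  # leakage guard: fitting on a subset does not center the held-out rows
  m2 <- matrix(withr::with_seed(2, rnorm(40, mean = 3)), 20, 2,
               dimnames = list(paste0("P", 1:20), c("a", "b")))
  st2 <- fitZScore(m2, rows = 1:10)
  zHeld <- applyZScore(m2[11:20, ], st2)
  expect_equal(mean(applyZScore(m2[1:10, ], st2)[, 1]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(zHeld[, 1])), 1e-6)
})

test_that("the structure stub is deterministic, length-preserving and
           helix-biased on poly-A", {
  s <- strrep("A", 40)
  ss <- predictSsStub(s)
  expect_equal(nchar(ss), 40)
  expect_gt(mean(strsplit(ss, "")[[1]] == "H"), 0.9)
  expect_identical(predictSsStub(s), ss)
  withr::with_seed(13, {
    for (i in 1:20) {
      sq <- paste(sample(GOSlimPred:::AA20, sample(5:80, 1), TRUE),
                  collapse = "")
      expect_equal(nchar(predictSsStub(sq)), nchar(sq))
    }
  })
})

test_that("Monte-Carlo ambiguity resolution converges to the closed-form
           expected features", {
  seq <- "ABZAXCJB"
  n <- 4000
  draws <- withr::with_seed(17, vapply(seq_len(n), function(i) {
    chars <- strsplit(seq, "")[[1]]
    amb <- !(chars %in% GOSlimPred:::AA20)
    chars[amb] <- vapply(chars[amb], function(cc) {
      comp <- tabs$ambiguity[[cc]]
      sample(comp, 1, prob = tabs$abundance[comp])
    }, "")
    paste(chars, collapse = "")
  }, ""))
  mcMono <- rowMeans(vapply(draws, monomerFrequencies, numeric(20),
                            tables = tabs))
  cf <- monomerFrequencies(seq, tabs)
  se <- sqrt(pmax(cf * (1 - cf), 1e-6) / (n * nchar(seq)))
  expect_true(all(abs(mcMono - cf) <= 3 * sqrt(cf * (1 - cf) / n) + 1e-3))
})
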