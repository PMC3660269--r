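#' Particle swarm settings for hyperparameter tuning
#'
#' Canonical PSO constants: inertia w, cognitive c1 and social c2
#' acceleration, swarm size and iteration count, and log10-scale search
#' boxes for the kernel width sigma and the penalty C.
#'
#' @param swarm number of particles (default 15).
#' @param iterations velocity/position updates (default 30).
#' @param w,c1,c2 inertia and acceleration constants (0.72, 1.49, 1.49 —
#'   the constriction-style defaults).
#' @param sigmaBounds,cBounds natural-scale boxes, searched in log10 space.
#' @return a `PsoSettings` list.
#' @export
psoSettings <- function(swarm = 15, iterations = 30, w = 0.72,
                        c1 = 1.49, c2 = 1.49,
                        sigmaBounds = c(1e-3, 1e3),
                        cBounds = c(1e-2, 1e3)) {
  stopifnot(all(sigmaBounds > 0), all(cBounds > 0),
            sigmaBounds[1] < sigmaBounds[2], cBounds[1] < cBounds[2])
  structure(list(swarm = swarm, iterations = iterations, w = w,
                 c1 = c1, c2 = c2,
                 lo = log10(c(sigmaBounds[1], cBounds[1])),
                 hi = log10(c(sigmaBounds[2], cBounds[2]))),
            class = "PsoSettings")
}

#' Tune (sigma, C) by particle swarm optimization
#'
#' Canonical PSO maximizing `objective(sigma, C)` over the log10-scale box
#' of `settings`: v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x),
#' x <- x + v, positions clamped to the bounds. Non-finite objective values
#' score -Inf and the run continues. Fully deterministic under `seed`.
#' With `iterations = 0` the best initial particle is returned.
#'
#' @param objective function(sigma, C) -> scalar score to maximize (here:
#'   mean inner-CV G-mean).
#' @param settings a [psoSettings] list.
#' @param seed RNG seed.
#' @return list `sigma`, `C`, `score`, `evaluations`.
#' @export
psoTune <- function(objective, settings = psoSettings(), seed = NULL) {
  lo <- settings$lo; hi <- settings$hi
  evalAt <- function(x) {
    v <- tryCatch(objective(10^x[1], 10^x[2]), error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  }
  withLocalSeed(seed, {
    n <- settings$swarm
    X <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]))
    V <- cbind(runif(n, -1, 1), runif(n, -1, 1)) * (hi - lo)[col(X)] * 0.1
    score <- apply(X, 1, evalAt)
    nev <- n
    P <- X; pScore <- score
    g <- which.max(pScore)
    G <- P[g, ]; gScore <- pScore[g]
    for (it in seq_len(settings$iterations)) {
      r1 <- matrix(runif(2 * n), n); r2 <- matrix(runif(2 * n), n)
      V <- settings$w * V + settings$c1 * r1 * (P - X) +
        settings$c2 * r2 * (matrix(G, n, 2, byrow = TRUE) - X)
      X <- X + V
      X[, 1] <- pmin(pmax(X[, 1], lo[1]), hi[1])
      X[, 2] <- pmin(pmax(X[, 2], lo[2]), hi[2])
      score <- apply(X, 1, evalAt)
      nev <- nev + n
      better <- score > pScore
      P[better, ] <- X[better, ]; pScore[better] <- score[better]
      g <- which.max(pScore)
      if (pScore[g] > gScore) { G <- P[g, ]; gScore <- pScore[g] }
    }
    list(sigma = 10^G[1], C = 10^G[2], score = gScore, evaluations = nev)
  })
}
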