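#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimizer following the standard
#' (mu/mu_w, lambda) scheme with rank-one and rank-mu covariance updates
#' and cumulative step-size adaptation. Box constraints are handled by
#' evaluating the objective at the coordinate-wise projection onto the box
#' and adding a quadratic penalty on the projection distance, so the
#' search distribution remains unconstrained while reported solutions are
#' always feasible.
#'
#' The caller controls randomness through R's RNG state (`set.seed()`
#' before the call); the routine draws only standard normal variates.
#'
#' @param fn objective function of a numeric vector; finite values
#'   required at feasible points.
#' @param x0 initial mean (numeric vector, inside the box).
#' @param sigma initial step size; default 0.25 of the (scaled) box width.
#' @param lower,upper box bounds (recycled to `length(x0)`).
#' @param popsize offspring per generation; default `4 + floor(3 log n)`.
#' @param max_iter maximum number of generations (default 500).
#' @param tol_fun stop when the spread of recent best values falls below
#'   this (default 1e-10).
#' @param penalty weight of the out-of-box quadratic penalty.
#' @param keep_trace logical; record per-generation best values.
#' @return List with `par` (best feasible point), `value`, `counts`
#'   (function evaluations), `iterations`, `converged`, and optionally
#'   `trace`.
#' @examples
#' set.seed(1)
#' res <- cmaes(function(x) sum((x - 0.3)^2), c(0.9, 0.9), 0.25, 0, 1)
#' res$par
#' @export
cmaes <- function(fn, x0, sigma = 0.25, lower = 0, upper = 1,
                  popsize = NULL, max_iter = 500, tol_fun = 1e-10,
                  penalty = 1e6, keep_trace = FALSE) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  stopifnot(all(lower < upper), all(x0 >= lower), all(x0 <= upper),
            sigma > 0)
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  invsqrtC <- diag(n)
  evalFeasible <- function(x) {
    xf <- pmin(pmax(x, lower), upper)
    f <- fn(xf)
    if (!is.finite(f)) f <- .Machine$double.xmax / 2
    list(f = f + penalty * sum((x - xf)^2), x = xf, fraw = f)
  }
  best <- evalFeasible(xmean)
  counts <- 1L
  hist_len <- 10L + ceiling(30 * n / lambda)
  fhist <- rep(NA_real_, hist_len)
  trace <- if (keep_trace) numeric(max_iter) else NULL
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    evals <- apply(arx, 2, evalFeasible)
    fs <- vapply(evals, `[[`, numeric(1), "f")
    counts <- counts + lambda
    ord <- order(fs)
    gb <- evals[[ord[1]]]
    if (gb$fraw < best$fraw) best <- gb

    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- drop(arx[, sel, drop = FALSE] %*% w)
    ymean <- (xmean - xold) / sigma

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * (invsqrtC %*% ymean)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * iter)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %*% t(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D2 <- pmax(eig$values, 1e-20)
    B <- eig$vectors
    D <- sqrt(D2)
    invsqrtC <- B %*% (t(B) / D)

    fhist[(iter - 1L) %% hist_len + 1L] <- fs[ord[1]]
    if (keep_trace) trace[iter] <- best$fraw
    if (iter >= hist_len &&
        diff(range(fhist, na.rm = TRUE)) < tol_fun) {
      converged <- TRUE
      break
    }
    if (sigma * max(D) < 1e-12) { converged <- TRUE; break }
  }
  list(par = best$x, value = best$fraw, counts = counts,
       iterations = iter, converged = converged,
       trace = if (keep_trace) trace[seq_len(iter)] else NULL)
}
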