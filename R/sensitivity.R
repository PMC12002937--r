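#' Uniform sensitivity ranges around an optimum
#'
#' Builds per-parameter uniform intervals `[theta*(1-f), theta*(1+f)]`
#' around calibrated values, the input distribution for the Sobol
#' analysis. A parameter at exactly 0 has no multiplicative scale; its
#' interval expands to `[0, f * zero_scale]`.
#'
#' @param optimum named numeric vector of calibrated parameter values.
#' @param fraction half-width as a fraction of the value (default 0.2,
#'   i.e. plus/minus 20%); must be > 0.
#' @param zero_scale absolute scale used for zero-valued parameters.
#' @return Named list of `c(lo, hi)` intervals.
#' @examples
#' makeRanges(c(r_prime = 0.062, d_prime = 0.068))
#' @export
makeRanges <- function(optimum, fraction = 0.2, zero_scale = 1) {
  stopifnot(is.numeric(optimum), length(optimum) >= 1L,
            !is.null(names(optimum)))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0)
    stop("'fraction' must be > 0 (zero-width ranges are degenerate)")
  out <- lapply(optimum, function(th) {
    if (th == 0) c(0, fraction * zero_scale)
    else sort(c(th * (1 - fraction), th * (1 + fraction)))
  })
  names(out) <- names(optimum)
  out
}

#' Pooled sensitivity ranges across material optima
#'
#' For parameters calibrated per material (the degradation constants),
#' the sensitivity interval spans from the smallest to the largest
#' optimum, each extended by the fractional margin.
#'
#' @param optima list of named numeric vectors (one per material).
#' @param fraction fractional extension (default 0.2).
#' @return Named list of `c(lo, hi)` intervals.
#' @export
pooledRanges <- function(optima, fraction = 0.2) {
  stopifnot(is.list(optima), length(optima) >= 1L)
  nm <- names(optima[[1]])
  out <- lapply(nm, function(p) {
    v <- vapply(optima, `[[`, numeric(1), p)
    c(min(v) * (1 - fraction), max(v) * (1 + fraction))
  })
  names(out) <- nm
  out
}

#' Sobol' low-discrepancy sequence
#'
#' Generates the first `n` points of the (unscrambled) Sobol' sequence in
#' `d` dimensions (including the origin), using the standard
#' direction-number table (primitive polynomials with Joe-Kuo initial
#' values, up to 30 dimensions) and the Antonov-Saleev Gray-code
#' construction. Quasi-random inputs are what make the Saltelli variance
#' estimators converge far faster than plain Monte Carlo at the same
#' sample count.
#'
#' @param n number of points (powers of 2 preserve dyadic balance).
#' @param d dimension (1-30).
#' @return `n x d` matrix of points in `[0, 1)`.
#' @export
sobolSequence <- function(n, d) {
  stopifnot(n >= 1L, d >= 1L, d <= 30L)
  B <- 31L
  poly <- c(1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L,
            67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L, 157L,
            167L, 171L, 185L, 191L, 193L, 203L)
  minit <- list(
    1L, 1L, c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
    c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
    c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
    c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
    c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
    c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
    c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
    c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
    c(1L, 3L, 5L, 9L, 1L, 25L, 53L), c(1L, 3L, 1L, 13L, 9L, 35L, 107L),
    c(1L, 3L, 1L, 5L, 27L, 61L, 31L), c(1L, 1L, 5L, 11L, 19L, 41L, 61L),
    c(1L, 3L, 5L, 3L, 3L, 13L, 69L), c(1L, 1L, 7L, 13L, 1L, 19L, 1L),
    c(1L, 3L, 7L, 5L, 13L, 19L, 59L), c(1L, 1L, 3L, 9L, 25L, 29L, 41L))
  V <- matrix(0L, B, d)
  for (j in seq_len(d)) {
    if (j == 1L) {
      V[, 1] <- bitwShiftL(1L, B - seq_len(B))
      next
    }
    m <- minit[[j]]
    s <- length(m)
    v <- integer(B)
    for (k in seq_len(min(s, B))) v[k] <- bitwShiftL(m[k], B - k)
    if (B > s) {
      pc <- poly[j]
      a <- vapply(seq_len(s - 1L), function(i)
        bitwAnd(bitwShiftR(pc, s - i), 1L), integer(1))
      for (k in (s + 1L):B) {
        vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
        for (i in seq_len(s - 1L))
          if (a[i] == 1L) vk <- bitwXor(vk, v[k - i])
        v[k] <- vk
      }
    }
    V[, j] <- v
  }
  X <- matrix(0L, n, d)
  x <- integer(d)
  if (n > 1L) for (i in 2:n) {
    k <- i - 2L  # rightmost zero bit of previous index
    c <- 1L
    while (bitwAnd(k, 1L) == 1L) { k <- bitwShiftR(k, 1L); c <- c + 1L }
    x <- bitwXor(x, V[c, ])
    X[i, ] <- x
  }
  X / 2^B
}

#' Saltelli cross-sampling design
#'
#' Generates the `n_base * (d + 2)` evaluation points of the Saltelli
#' scheme for first-order and total-effect indices (second-order terms
#' off): base matrices A and B taken from a `2d`-dimensional Sobol'
#' sequence, followed by the d hybrid matrices AB_i, where column i of A
#' is replaced by column i of B. The seed applies a Cranley-Patterson
#' rotation (a random shift modulo 1), which preserves the
#' low-discrepancy structure while making independent replicates
#' possible; the caller's RNG state is restored.
#'
#' @param ranges named list of `c(lo, hi)` intervals.
#' @param n_base base sample count N (powers of 2 recommended).
#' @param seed optional integer seed for the rotation (`NULL` = plain
#'   sequence).
#' @return Matrix of size `n_base*(d+2) x d` with attributes `n_base` and
#'   `block` (`"A"`, `"B"`, `"AB1"`, ...).
#' @export
saltelliSample <- function(ranges, n_base, seed = NULL) {
  d <- length(ranges)
  stopifnot(d >= 1L, n_base >= 2L)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("degenerate ranges: need lo < hi")
  U <- sobolSequence(n_base, 2L * d)
  if (!is.null(seed)) {
    shift <- withSeed(seed, stats::runif(2L * d))
    U <- sweep(U, 2, shift, `+`) %% 1
  }
  A <- U[, seq_len(d), drop = FALSE]
  B <- U[, d + seq_len(d), drop = FALSE]
  blocks <- vector("list", d + 2L)
  blocks[[1]] <- A; blocks[[2]] <- B
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    blocks[[i + 2L]] <- ABi
  }
  X <- do.call(rbind, blocks)
  X <- sweep(sweep(X, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(X) <- names(ranges)
  attr(X, "n_base") <- as.integer(n_base)
  attr(X, "block") <- rep(c("A", "B", paste0("AB", seq_len(d))),
                          each = n_base)
  X
}

#' Sobol indices from Saltelli design outputs
#'
#' First-order indices via the Saltelli (2010) estimator
#' `Si = mean(yB * (yABi - yA)) / V` and total-effect indices via the
#' Jansen estimator `STi = mean((yA - yABi)^2) / (2 V)`, with
#' `V = var(c(yA, yB))`. Optional bootstrap (resampling base-sample
#' indices) yields percentile confidence intervals.
#'
#' @param design matrix from [saltelliSample()].
#' @param y numeric outputs, one per design row (finite).
#' @param n_boot bootstrap replicates for confidence intervals (0 = none).
#' @param conf confidence level for the intervals.
#' @param si_threshold,sti_threshold influence thresholds (a parameter is
#'   flagged influential when `Si >= si_threshold` or
#'   `STi >= sti_threshold`).
#' @return An object of class `osteo_sobol`: data frame with `parameter`,
#'   `Si`, `STi`, optional CI columns, and `influential`.
#' @export
sobolIndices <- function(design, y, n_boot = 0, conf = 0.95,
                         si_threshold = 0.05, sti_threshold = 0.1) {
  n <- attr(design, "n_base")
  if (is.null(n)) stop("'design' must come from saltelliSample()")
  d <- ncol(design)
  if (length(y) != n * (d + 2L)) stop("'y' length does not match design")
  if (any(!is.finite(y))) stop("non-finite model outputs")
  yA <- y[seq_len(n)]
  yB <- y[n + seq_len(n)]
  yAB <- matrix(y[-seq_len(2L * n)], nrow = n, ncol = d)
  est <- function(idx) {
    V <- stats::var(c(yA[idx], yB[idx]))
    if (V <= 0) stop("zero output variance: model is constant over ranges")
    Si <- vapply(seq_len(d), function(i)
      mean(yB[idx] * (yAB[idx, i] - yA[idx])) / V, numeric(1))
    STi <- vapply(seq_len(d), function(i)
      mean((yA[idx] - yAB[idx, i])^2) / (2 * V), numeric(1))
    cbind(Si, STi)
  }
  point <- est(seq_len(n))
  res <- data.frame(parameter = colnames(design),
                    Si = point[, 1], STi = point[, 2])
  if (n_boot > 0) {
    boots <- replicate(n_boot, est(sample.int(n, n, replace = TRUE)))
    a <- (1 - conf) / 2
    res$Si_lo <- apply(boots[, 1, ], 1, stats::quantile, probs = a)
    res$Si_hi <- apply(boots[, 1, ], 1, stats::quantile, probs = 1 - a)
    res$STi_lo <- apply(boots[, 2, ], 1, stats::quantile, probs = a)
    res$STi_hi <- apply(boots[, 2, ], 1, stats::quantile, probs = 1 - a)
  }
  res$influential <- res$Si >= si_threshold | res$STi >= sti_threshold
  attr(res, "n_base") <- n
  class(res) <- c("osteo_sobol", "data.frame")
  res
}

#' @export
print.osteo_sobol <- function(x, ...) {
  cat("Sobol sensitivity indices (base sample N =", attr(x, "n_base"),
      ")\n")
  NextMethod()
}

#' Influence classification
#'
#' @param result an `osteo_sobol` data frame.
#' @param si_threshold first-order threshold (default 0.05).
#' @param sti_threshold total-effect threshold (default 0.1).
#' @return Logical vector named by parameter.
#' @export
classifyInfluential <- function(result, si_threshold = 0.05,
                                sti_threshold = 0.1) {
  stats::setNames(result$Si >= si_threshold |
                    result$STi >= sti_threshold, result$parameter)
}

#' Scalar model output for sensitivity analysis
#'
#' Reduces a model trajectory to the scalar the variance decomposition is
#' computed on. The default is the mean of the chosen variable over the
#' experimental time grid; the value at the final time or the L2 norm are
#' available as alternatives.
#'
#' @param params named vector overriding entries of the scenario's
#'   parameter sets (degradation, remodelling and/or ultrastructure
#'   names).
#' @param scenario list with elements `variable` (`"vloss"`, `"bvtv"`,
#'   `"cwidth"` or `"lattice"`), `times` (evaluation grid), and baseline
#'   parameter objects `degradation`, `remodelling`, `ultrastructure` as
#'   needed; optional `H0` and `summary`.
#' @param summary `"mean"` (default), `"final"` or `"l2"`.
#' @return A scalar.
#' @export
modelOutputScalar <- function(params, scenario,
                              summary = c("mean", "final", "l2")) {
  if (missing(summary) && !is.null(scenario$summary))
    summary <- scenario$summary
  summary <- match.arg(summary, c("mean", "final", "l2"))
  v <- scenario$variable
  tt <- scenario$times
  override <- function(obj, build) {
    if (is.null(obj)) return(NULL)
    th <- unclass(obj)
    hit <- intersect(names(params), names(th))
    th[hit] <- params[hit]
    build(th)
  }
  deg <- override(scenario$degradation, function(th) {
    if (th$model == "power_law")
      degradationParams("power_law", m1 = th$m1, eps_t = th$eps_t,
                        exponent = th$exponent)
    else degradationParams("surface_rate", r_prime = th$r_prime,
                           d_prime = th$d_prime, eps_t = th$eps_t,
                           exponent = th$exponent)
  })
  if (v == "vloss") {
    y <- volumeLoss(deg, tt)
  } else {
    rem <- override(scenario$remodelling, function(th)
      remodellingParams(k1 = th$k1, v1 = th$v1, r1 = th$r1, k3 = th$k3,
                        r2 = th$r2, m2 = th$m2, k2 = th$k2, a = th$a,
                        b = th$b,
                        inhibitor_removal = th$inhibitor_removal))
    ult <- override(scenario$ultrastructure, function(th)
      ultrastructureParams(k4 = th$k4, k6 = th$k6, k7 = th$k7, k8 = th$k8,
                           plane = th$plane, L_min = th$L_min,
                           L_max = th$L_max, C_hat = th$C_hat,
                           C0 = th$C0))
    tr <- simulateModel(rem, deg, ult,
                        times = sort(unique(c(0, tt))),
                        H0 = scenario$H0 %||here% 0)
    col <- c(bvtv = "H", cwidth = "Cwidth", lattice = "L")[[v]]
    y <- tr[[col]][match(tt, tr$time)]
  }
  switch(summary, mean = mean(y), final = y[length(y)],
         l2 = sqrt(sum(y^2)))
}

`%||here%` <- function(a, b) if (is.null(a)) b else a

#' Full Sobol sensitivity analysis of a model scalar
#'
#' Convenience orchestrator: Saltelli design over the ranges, model
#' evaluation through [modelOutputScalar()] (or any user function), and
#' index estimation.
#'
#' @param ranges named list of `c(lo, hi)` intervals.
#' @param model either a function of a named parameter vector returning a
#'   scalar, or a scenario list for [modelOutputScalar()].
#' @param n_base base sample count (2^10 is adequate for screening;
#'   2^14 for production runs).
#' @param seed integer seed.
#' @param n_boot bootstrap replicates.
#' @param ... passed to [sobolIndices()].
#' @return An `osteo_sobol` data frame.
#' @export
sobolAnalysis <- function(ranges, model, n_base = 1024L, seed = 1,
                          n_boot = 0, ...) {
  X <- saltelliSample(ranges, n_base, seed)
  f <- if (is.function(model)) model else
    function(p) modelOutputScalar(p, model)
  y <- vapply(seq_len(nrow(X)), function(i) f(X[i, ]), numeric(1))
  sobolIndices(X, y, n_boot = n_boot, ...)
}
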