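#' Bone remodelling (mineralization) parameters
#'
#' Rate constants of the extended Komarova-type mineralization system:
#' naive collagen matrix `x1` matures into `x2` at rate `k1`; a generalized
#' inhibitor `I` is produced through the naive matrix at rate `v1` and
#' removed at rate `r1`; active nucleators `N` are created with maturation
#' (`k2` per event) and encapsulated by growing mineral at rate `r2`;
#' mineral `H` (identified with BV/TV) grows at rate `k3`, gated by a Hill
#' function of the inhibitor with exponent `a` and constant `b`. For
#' Mg-based implants, released Mg2+ ions add to the inhibitor pool at an
#' effective rate `m2` times the volume-loss rate; `m2 = 0` for permanent
#' (Ti) implants.
#'
#' Two removal terms for the inhibitor are available. The default,
#' `"mature_matrix"`, removes inhibitor in proportion to the amount of
#' mature matrix present (`-r1 * x2 * I`), so removal persists after the
#' matrix has matured; this is required for the inhibitor spike caused by
#' Mg degradation to decay and mineralization to resume. The alternative
#' `"maturation_rate"` ties removal to maturation events
#' (`-r1 * (k1 x1) * I`), which shuts off once `x1` has decayed.
#'
#' @param k1 collagen matrix maturation rate (1/day), > 0.
#' @param v1 inhibitor production rate (1/day), > 0.
#' @param r1 inhibitor removal rate (1/day), > 0.
#' @param k3 bone growth rate (BV/TV units per day), > 0.
#' @param r2 nucleator encapsulation rate (per unit mineral), > 0.
#' @param m2 effective Mg-inhibition rate, >= 0 (0 for Ti).
#' @param k2 nucleators created per maturation event; fixed at 1.
#' @param a Hill exponent; fixed at 10.
#' @param b Hill constant; fixed at 0.001.
#' @param inhibitor_removal `"mature_matrix"` (default) or
#'   `"maturation_rate"`; see Details.
#' @return An object of class `osteo_remodelling`.
#' @examples
#' remodellingParams(k1 = 0.388, v1 = 0.0164, r1 = 0.4915,
#'                   r2 = 23.1846, k3 = 0.5744)
#' @export
remodellingParams <- function(k1, v1, r1, k3, r2, m2 = 0,
                              k2 = 1, a = 10, b = 0.001,
                              inhibitor_removal = c("mature_matrix",
                                                    "maturation_rate")) {
  inhibitor_removal <- match.arg(inhibitor_removal)
  num1 <- function(x, nm, lo = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number")
    if (strict && x <= lo) stop("'", nm, "' must be > ", lo)
    if (!strict && x < lo) stop("'", nm, "' must be >= ", lo)
    x
  }
  structure(
    list(k1 = num1(k1, "k1"), v1 = num1(v1, "v1"), r1 = num1(r1, "r1"),
         k3 = num1(k3, "k3"), r2 = num1(r2, "r2"),
         m2 = num1(m2, "m2", strict = FALSE),
         k2 = num1(k2, "k2"), a = num1(a, "a"), b = num1(b, "b"),
         inhibitor_removal = inhibitor_removal),
    class = "osteo_remodelling"
  )
}

#' @export
print.osteo_remodelling <- function(x, ...) {
  cat("Bone remodelling parameters (1/day):\n")
  cat(sprintf("  k1 = %.4g  v1 = %.4g  r1 = %.4g  m2 = %.4g\n",
              x$k1, x$v1, x$r1, x$m2))
  cat(sprintf("  r2 = %.4g  k3 = %.4g  (k2 = %g, Hill a = %g, b = %g)\n",
              x$r2, x$k3, x$k2, x$a, x$b))
  cat("  inhibitor removal:", x$inhibitor_removal, "\n")
  invisible(x)
}

#' Hill gate of the inhibitor
#'
#' `b / (b + I^a)`: close to 1 when the inhibitor is depleted, close to 0
#' while `I` is of order 1 or larger (for the default `a = 10`,
#' `b = 0.001`).
#'
#' @param I inhibitor concentration(s), >= 0.
#' @param a Hill exponent.
#' @param b Hill constant.
#' @return Values in `(0, 1]`; equal to 1 iff `I = 0`.
#' @export
hillGate <- function(I, a = 10, b = 0.001) b / (b + I^a)

#' Right-hand side of the remodelling system
#'
#' Derivatives of `(x1, x2, I, N, H)` at time `t`. `dH/dt` is computed
#' first and substituted into the nucleator equation, so no algebraic loop
#' exists. The Mg coupling enters the inhibitor equation as
#' `+ m2 * vloss_rate(t)`.
#'
#' @param state named numeric vector with components `x1, x2, I, N, H`.
#' @param t time (days).
#' @param params an [remodellingParams()] object.
#' @param vloss_rate function of `t` returning the volume-loss rate
#'   (use [volumeLossRateFunction()]); defaults to zero (permanent implant).
#' @return Named numeric vector `(dx1, dx2, dI, dN, dH)`.
#' @export
remodellingRHS <- function(state, t, params, vloss_rate = function(t) 0) {
  if (any(!is.finite(state))) stop("non-finite state passed to remodellingRHS")
  x1 <- state[["x1"]]; x2 <- state[["x2"]]
  I <- state[["I"]]; N <- state[["N"]]
  p <- params
  dx1 <- -p$k1 * x1
  dx2 <- p$k1 * x1
  dH <- p$k3 * hillGate(I, p$a, p$b) * N
  dN <- p$k2 * p$k1 * x1 - p$r2 * dH * N
  removal <- if (p$inhibitor_removal == "mature_matrix") p$r1 * x2 * I
             else p$r1 * (p$k1 * x1) * I
  dI <- p$v1 * x1 - removal + p$m2 * vloss_rate(t)
  c(dx1 = dx1, dx2 = dx2, dI = dI, dN = dN, dH = dH)
}

#' Simulate the remodelling system
#'
#' Integrates `(x1, x2, I, N, H)` coupled to an analytic degradation-rate
#' function (never a numerical derivative of the cumulative loss). A thin
#' wrapper over [simulateModel()] without the ultrastructure block.
#'
#' @param params an [remodellingParams()] object.
#' @param degradation an [degradationParams()] object or `NULL` (no
#'   degradation; Ti case).
#' @param times strictly increasing output grid starting at 0 (days).
#' @param H0 initial mineral content `H(0)` (BV/TV units), default 0.
#' @param ... passed to [simulateModel()] (e.g. `rtol`, `atol`).
#' @return An `osteo_trajectory` data frame.
#' @export
simulateRemodelling <- function(params, degradation = NULL, times,
                                H0 = 0, ...) {
  simulateModel(remodelling = params, degradation = degradation,
                ultrastructure = NULL, times = times, H0 = H0, ...)
}

#' Mineralization lag time
#'
#' Growth-curve lag: the tangent to `H(t)` at the point of maximum slope is
#' intersected with the baseline `H = H(0)`; the intersection time is the
#' lag. Uses the exact `dHdt` column when present (written by
#' [simulateModel()]), otherwise central finite differences.
#'
#' @param trajectory a data frame with columns `time` and `H` (and
#'   optionally `dHdt`).
#' @return Lag time in days.
#' @export
computeLag <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("time", "H") %in% names(trajectory)))
  tt <- trajectory$time
  H <- trajectory$H
  if (diff(range(H)) <= .Machine$double.eps * max(1, abs(H[1])))
    stop("flat trajectory: lag time is undefined (no growth phase)")
  if ("dHdt" %in% names(trajectory)) {
    slope <- trajectory$dHdt
  } else {
    n <- length(tt)
    slope <- c(diff(H[1:2]) / diff(tt[1:2]),
               (H[-(1:2)] - H[1:(n - 2)]) / (tt[-(1:2)] - tt[1:(n - 2)]),
               diff(H[(n - 1):n]) / diff(tt[(n - 1):n]))
  }
  i <- which.max(slope)
  if (slope[i] <= 0) stop("flat trajectory: lag time is undefined")
  tt[i] - (H[i] - H[1]) / slope[i]
}
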