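#' Hydroxyapatite ultrastructure parameters
#'
#' Kinetics of the crystal width and the lattice spacing. The crystal
#' width (normalized by 15 nm) grows multiplicatively with the
#' mineralization rate, `dCw/dt = k4 * Cw * (dH/dt)^k6`, where `k6 >= 1`
#' is the order of the precipitation process and `k4` absorbs the
#' crystallization constant, the surface-area proportionality and the
#' supersaturation scale. The lattice spacing `L` (in Angstrom, for the
#' (310) or (002) plane) shrinks toward a theoretical minimum `L_min`
#' while Mg2+ substitutes Ca2+ at a rate `k7` proportional to the
#' volume-loss rate, and relaxes back toward the healthy spacing `L_max`
#' at a removal rate `k8`:
#' `dL/dt = -k7 * dVloss/dt * (L - L_min) + k8 * (L_max - L)`.
#'
#' Plane defaults: (002) `L_min = 3.403`, `L_max = 3.447`; (310)
#' `L_min = 2.243`, `L_max = 2.281` (Angstrom); both overridable.
#'
#' The initial width `C0` seeds the multiplicative growth law (an exactly
#' zero width would be an absorbing state); it is confounded with the
#' overall scale of the fitted `k4`/width curve.
#'
#' @param k4 crystal growth prefactor, > 0.
#' @param k6 order of the precipitation process, >= 1.
#' @param k7 Ca2+ substitution rate per unit volume loss, > 0.
#' @param k8 Mg2+ removal rate (1/day), > 0.
#' @param plane `"002"` or `"310"`.
#' @param L_min,L_max lattice-spacing bounds (Angstrom); defaults by plane.
#' @param C_hat crystal-width normalization (nm), default 15.
#' @param C0 initial normalized crystal width seed, in (0, 1); default 1e-3.
#' @return An object of class `osteo_ultrastructure`.
#' @examples
#' ultrastructureParams(k4 = 38.1357, k6 = 1.2694, k7 = 2.3037, k8 = 0.0092)
#' @export
ultrastructureParams <- function(k4, k6, k7, k8, plane = c("002", "310"),
                                 L_min = NULL, L_max = NULL,
                                 C_hat = 15, C0 = 1e-3) {
  plane <- match.arg(plane)
  defaults <- list(`002` = c(3.403, 3.447), `310` = c(2.243, 2.281))
  if (is.null(L_min)) L_min <- defaults[[plane]][1]
  if (is.null(L_max)) L_max <- defaults[[plane]][2]
  num1 <- function(x, nm, lo = 0) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= lo)
      stop("'", nm, "' must be a single finite number > ", lo)
    x
  }
  num1(k4, "k4"); num1(k7, "k7"); num1(k8, "k8"); num1(C_hat, "C_hat")
  if (!is.numeric(k6) || length(k6) != 1L || !is.finite(k6) || k6 < 1)
    stop("'k6' must be a single finite number >= 1")
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) ||
      C0 <= 0 || C0 >= 1)
    stop("'C0' must lie in (0, 1)")
  if (!is.finite(L_min) || !is.finite(L_max) || L_min >= L_max)
    stop("'L_min' must be smaller than 'L_max'")
  structure(
    list(k4 = k4, k6 = k6, k7 = k7, k8 = k8, plane = plane,
         L_min = L_min, L_max = L_max, C_hat = C_hat, C0 = C0),
    class = "osteo_ultrastructure"
  )
}

#' @export
print.osteo_ultrastructure <- function(x, ...) {
  cat("Hydroxyapatite ultrastructure parameters, plane (", x$plane, "):\n",
      sep = "")
  cat(sprintf("  k4 = %.4g  k6 = %.4g  k7 = %.4g  k8 = %.4g\n",
              x$k4, x$k6, x$k7, x$k8))
  cat(sprintf("  L in [%.3f, %.3f] A;  C_hat = %g nm;  C0 = %g\n",
              x$L_min, x$L_max, x$C_hat, x$C0))
  invisible(x)
}

#' Right-hand side of the ultrastructure equations
#'
#' @param Cw normalized crystal width, >= 0.
#' @param L lattice spacing (Angstrom) within `[L_min, L_max]`.
#' @param t time (days).
#' @param params an [ultrastructureParams()] object.
#' @param dH_dt function of `t` giving the mineralization rate (>= 0;
#'   tiny negative values from numerics are clipped to 0).
#' @param vloss_rate function of `t` giving the volume-loss rate.
#' @return Named numeric vector `(dCw, dL)`.
#' @export
ultrastructureRHS <- function(Cw, L, t, params, dH_dt,
                              vloss_rate = function(t) 0) {
  p <- params
  if (L < p$L_min - 1e-9 || L > p$L_max + 1e-9)
    stop("lattice spacing outside [L_min, L_max]")
  h <- max(dH_dt(t), 0)
  c(dCw = p$k4 * Cw * h^p$k6,
    dL = -p$k7 * vloss_rate(t) * (L - p$L_min) + p$k8 * (p$L_max - L))
}

#' Closed-form crystal width
#'
#' The width equation is separable:
#' `Cw(t) = C0 * exp(k4 * integral_0^t (dH/ds)^k6 ds)`, with the integral
#' evaluated by adaptive quadrature. Serves as the independent oracle for
#' the joint ODE solve.
#'
#' @param params an [ultrastructureParams()] object.
#' @param dH_dt function of time giving the mineralization rate (>= 0).
#' @param t time(s) at which to evaluate (days).
#' @param ... passed to [stats::integrate()] (e.g. `rel.tol`).
#' @return Numeric vector `Cw(t)`.
#' @export
crystalWidthClosedForm <- function(params, dH_dt, t, ...) {
  stopifnot(inherits(params, "osteo_ultrastructure"))
  checkTimes(t)
  integrand <- function(s) pmax(dH_dt(s), 0)^params$k6
  vapply(t, function(ti) {
    v <- if (ti == 0) 0 else
      safeIntegrate(integrand, 0, ti, ...)
    params$C0 * exp(params$k4 * v)
  }, numeric(1))
}

#' Closed-form lattice spacing
#'
#' The lattice equation is linear first-order with coefficient
#' `a(t) = k7 * v(t) + k8` and forcing
#' `b(t) = k7 * v(t) * L_min + k8 * L_max`. With `M = L - L_min` and
#' `A(t) = k7 * Vloss(t) + k8 * t` the integrating-factor solution from
#' `L(0) = L_max` is
#' `L(t) = L_min + (L_max - L_min) * (exp(-A(t)) + k8 * I(t))`,
#' `I(t) = integral_0^t exp(A(s) - A(t)) ds`, whose integrand is bounded by
#' 1, so the quadrature is overflow-safe. When `degradation` is a parameter
#' object the exponent uses the analytic cumulative loss; a plain rate
#' function is also accepted (its integral is then computed by quadrature).
#'
#' @param params an [ultrastructureParams()] object.
#' @param degradation an [degradationParams()] object, a rate function of
#'   time, or `NULL` (no corrosion).
#' @param t time(s) at which to evaluate (days).
#' @return Numeric vector `L(t)`, always within `[L_min, L_max]`.
#' @export
latticeClosedForm <- function(params, degradation, t) {
  stopifnot(inherits(params, "osteo_ultrastructure"))
  checkTimes(t)
  p <- params
  if (is.null(degradation)) {
    V <- function(s) rep(0, length(s))
  } else if (inherits(degradation, "osteo_degradation")) {
    V <- function(s) volumeLoss(degradation, s)
  } else if (is.function(degradation)) {
    rate <- degradation
    V <- function(s) vapply(s, function(si) {
      if (si == 0) 0 else safeIntegrate(rate, 0, si)
    }, numeric(1))
  } else stop("'degradation' must be parameters, a rate function, or NULL")
  A <- function(s) p$k7 * V(s) + p$k8 * s
  delta <- p$L_max - p$L_min
  vapply(t, function(ti) {
    At <- A(ti)
    I <- if (ti == 0) 0 else
      safeIntegrate(function(s) exp(A(s) - At), 0, ti)
    L <- p$L_min + delta * (exp(-At) + p$k8 * I)
    min(max(L, p$L_min), p$L_max)
  }, numeric(1))
}

# adaptive quadrature robust to the kinks of interpolated rate
# functions: Gauss-Kronrod first, QAGS as fallback
safeIntegrate <- function(f, lower, upper, rel.tol = 1e-10, ...) {
  v <- tryCatch(pracma::quadgk(f, lower, upper, tol = rel.tol),
                error = function(e) NULL)
  if (!is.null(v) && is.finite(v)) return(v)
  for (tol in c(1e-9, 1e-7)) {
    v <- tryCatch(
      stats::integrate(f, lower, upper, rel.tol = tol,
                       subdivisions = 1000L, ...)$value,
      error = function(e) NULL)
    if (!is.null(v)) return(v)
  }
  stop("adaptive quadrature failed on [", lower, ", ", upper, "]")
}
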