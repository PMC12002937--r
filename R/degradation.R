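#' Implant degradation (volume-loss) model parameters
#'
#' Two kinetic laws for the volume loss of a biodegradable implant are
#' supported. The diffusion-limited power law gives a rate
#' `dVloss/dt = m1 / sqrt(t)`, regularized near `t = 0` by a small offset
#' `eps_t`. The surface-rate law accounts for the protective effect of
#' precipitated degradation products and gives
#' `dVloss/dt = r' d' / (r' t + d')`, where `r'` is the effective surface
#' corrosion rate (1/day) and `d'` the effective precipitated-material
#' fraction, both already scaled by the implant's initial surface-to-volume
#' ratio. Volume loss is carried as a fraction in `[0, 1)`; conversion to
#' percent happens only at the I/O boundary.
#'
#' @param model `"surface_rate"` or `"power_law"`.
#' @param m1 scaled diffusion coefficient (power law only), `>= 0`.
#' @param r_prime effective surface corrosion rate, 1/day (surface-rate law).
#' @param d_prime effective precipitated-material fraction (surface-rate law).
#' @param eps_t small positive time offset regularizing the power law at
#'   `t = 0`. Default `1e-30`.
#' @param exponent power-law exponent `p` in `dVloss/dt = m1 * (t+eps_t)^p`;
#'   default `-0.5` (diffusion limitation). Must lie in `(-1, 0]`.
#' @return An object of class `osteo_degradation`.
#' @examples
#' degradationParams("surface_rate", r_prime = 0.062, d_prime = 0.068)
#' degradationParams("power_law", m1 = 0.015)
#' @export
degradationParams <- function(model = c("surface_rate", "power_law"),
                              m1 = NULL, r_prime = NULL, d_prime = NULL,
                              eps_t = 1e-30, exponent = -0.5) {
  model <- match.arg(model)
  stopifnot(is.numeric(eps_t), length(eps_t) == 1L, is.finite(eps_t), eps_t > 0)
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent),
            exponent > -1, exponent <= 0)
  if (model == "power_law") {
    if (is.null(m1)) stop("'m1' is required for the power_law model")
    if (!is.numeric(m1) || length(m1) != 1L || !is.finite(m1) || m1 < 0)
      stop("'m1' must be a single finite number >= 0")
  } else {
    if (is.null(r_prime) || is.null(d_prime))
      stop("'r_prime' and 'd_prime' are required for the surface_rate model")
    if (!is.numeric(r_prime) || length(r_prime) != 1L || !is.finite(r_prime) ||
        r_prime <= 0)
      stop("'r_prime' must be a single finite number > 0")
    if (!is.numeric(d_prime) || length(d_prime) != 1L || !is.finite(d_prime) ||
        d_prime <= 0)
      stop("'d_prime' must be a single finite number > 0")
  }
  structure(
    list(model = model, m1 = m1, r_prime = r_prime, d_prime = d_prime,
         eps_t = eps_t, exponent = exponent),
    class = "osteo_degradation"
  )
}

#' @export
print.osteo_degradation <- function(x, ...) {
  cat("Implant degradation model:", x$model, "\n")
  if (x$model == "power_law") {
    cat("  m1 =", x$m1, " exponent =", x$exponent, " eps_t =", x$eps_t, "\n")
  } else {
    cat("  r' =", x$r_prime, "/day   d' =", x$d_prime, "\n")
  }
  invisible(x)
}

checkTimes <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("time values must be finite numbers")
  if (any(t < 0)) stop("time values must be >= 0")
  t
}

#' Instantaneous volume-loss rate
#'
#' Evaluates `dVloss/dt` at time `t` (days) for either degradation law. The
#' rate is nonnegative and non-increasing in `t` for both laws.
#'
#' @param params an [degradationParams()] object.
#' @param t nonnegative time(s) in days.
#' @return Numeric vector of rates (volume fraction per day).
#' @examples
#' p <- degradationParams("surface_rate", r_prime = 0.062, d_prime = 0.068)
#' volumeLossRate(p, 0)   # equals r' at t = 0
#' @export
volumeLossRate <- function(params, t) {
  stopifnot(inherits(params, "osteo_degradation"))
  checkTimes(t)
  if (params$model == "power_law") {
    params$m1 * (t + params$eps_t)^params$exponent
  } else {
    with(params, r_prime * d_prime / (r_prime * t + d_prime))
  }
}

#' Cumulative volume loss (closed form)
#'
#' Analytic antiderivative of [volumeLossRate()] with `Vloss(0) = 0`.
#' Power law: `m1/(p+1) * ((t+eps)^(p+1) - eps^(p+1))` (for the default
#' `p = -1/2` this is `2 m1 (sqrt(t+eps) - sqrt(eps))`). Surface-rate law:
#' `d' * log(1 + r' t / d')`.
#'
#' @inheritParams volumeLossRate
#' @return Numeric vector of cumulative volume-loss fractions.
#' @examples
#' p <- degradationParams("power_law", m1 = 0.015)
#' volumeLoss(p, 100)  # 2 * 0.015 * 10
#' @export
volumeLoss <- function(params, t) {
  stopifnot(inherits(params, "osteo_degradation"))
  checkTimes(t)
  if (params$model == "power_law") {
    q <- params$exponent + 1
    params$m1 / q * ((t + params$eps_t)^q - params$eps_t^q)
  } else {
    with(params, d_prime * log1p(r_prime * t / d_prime))
  }
}

#' Volume-loss rate as a plain function of time
#'
#' Convenience closure used to couple a degradation model into the
#' remodelling and ultrastructure right-hand sides.
#'
#' @inheritParams volumeLossRate
#' @return A function `f(t)` returning the rate.
#' @export
volumeLossRateFunction <- function(params) {
  if (is.null(params)) return(function(t) rep(0, length(t)))
  stopifnot(inherits(params, "osteo_degradation"))
  function(t) volumeLossRate(params, t)
}
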