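#' Continuous diffusion solution for body mass
#'
#' Closed-form solution of the diffusion equation
#' \eqn{\partial V/\partial t = D\,\partial^2 V/\partial x^2} with boundary
#' mass \eqn{V_s = E/p} held at \eqn{x = 0} and initial mass \eqn{V_0}
#' elsewhere:
#' \deqn{V(x,t) = (E/p)\,[1 - \mathrm{erf}(x / 2\sqrt{Dt})]
#'              + V_0\,\mathrm{erf}(x / 2\sqrt{Dt}).}
#' The result is always a convex combination of `V0` and `E/p`: at `x = 0`
#' it equals `E/p`, and as `t -> 0+` (with `x > 0`) it tends to `V0`.
#'
#' @param V0 initial body mass (kg).
#' @param E net energy intake (kcal).
#' @param p energy density of fat mass (kcal/kg), > 0.
#' @param D diffusion coefficient (length^2/time), > 0.
#' @param x distance (length), >= 0.
#' @param t time, > 0.
#' @return body mass (kg), between `min(V0, E/p)` and `max(V0, E/p)`.
#' @examples
#' continuous_weight(V0 = 70, E = 50 * 9400, p = 9400, D = 1, x = 0, t = 1)
#' @export
continuous_weight <- function(V0, E, p, D, x, t) {
  if (!is.finite(V0) || !is.finite(E)) stop("'V0' and 'E' must be finite")
  if (p <= 0) stop("fat energy density 'p' must be positive")
  if (D <= 0) stop("diffusion coefficient 'D' must be positive")
  if (any(t <= 0)) stop("time 't' must be positive")
  if (any(x < 0)) stop("distance 'x' must be non-negative")
  w <- erf(x / (2 * sqrt(D * t)))
  (E / p) * (1 - w) + V0 * w
}

#' Model constants for the weekly weight recursion
#'
#' Bundles the two fitted constants and the initial weight of the discrete
#' recursion `f(t) = f(t-1) erf(beta) + 7 alpha l(t) [1 - erf(beta)]`,
#' where `l(t)` is the week's daily net energy intake (kcal/day) and the
#' factor 7 converts it to a weekly energy scale.
#'
#' @param alpha intake-to-steady-weight scale, kg per (kcal/day); the
#'   steady-state weight under constant intake `l` is `7 * alpha * l`.
#' @param beta dimensionless erf argument, >= 0; `erf(beta)` is the weekly
#'   weight-persistence fraction.
#' @param initial_weight starting body weight `b` (kg), > 0.
#' @return an object of class `"diffusion_params"`.
#' @export
diffusion_params <- function(alpha, beta, initial_weight) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(initial_weight))
  if (beta < 0) stop("'beta' must be non-negative")
  if (initial_weight <= 0) stop("'initial_weight' must be positive")
  structure(list(alpha = alpha, beta = beta, initial_weight = initial_weight),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("diffusion recursion constants: alpha = %.6g, beta = %.6g (erf(beta) = %.4f), b = %.4g kg\n",
              x$alpha, x$beta, erf(x$beta), x$initial_weight))
  invisible(x)
}

#' One week of the weight recursion
#'
#' Advances body weight by one week:
#' `erf(beta) * prev_weight + 7 * alpha * net_intake * (1 - erf(beta))`.
#' Linear in both `prev_weight` and `net_intake`; vectorised over all
#' arguments.
#'
#' @param prev_weight previous week's body weight (kg).
#' @param net_intake daily net energy intake during the week (kcal/day).
#' @param alpha,beta model constants (see [diffusion_params()]).
#' @return next week's body weight (kg).
#' @examples
#' weight_step(69.39, -226.53, alpha = 0.016337, beta = 1.7096)  # ~67.90
#' @export
weight_step <- function(prev_weight, net_intake, alpha, beta) {
  if (any(beta < 0)) stop("'beta' must be non-negative")
  e <- erf(beta)
  prev_weight * e + 7 * alpha * net_intake * (1 - e)
}

#' Simulate a weekly weight trajectory
#'
#' Iterates [weight_step()] over a schedule of weekly net intakes.  In
#' `"chained"` mode each prediction is fed back as the next step's previous
#' weight (the forecasting mode used for all headline fits); in
#' `"one_step_ahead"` mode the previous week's *observed* weight is used
#' instead, which requires `observed`.
#'
#' @param net_intake vector of daily net intakes (kcal/day), one per week.
#' @param alpha,beta model constants.
#' @param initial_weight weight at the week preceding the first intake (kg).
#' @param mode `"chained"` (default) or `"one_step_ahead"`.
#' @param observed observed weights aligned with `net_intake`; only needed
#'   (and only used) in one-step-ahead mode, where week `t`'s prediction
#'   starts from `observed[t - 1]` (and from `initial_weight` at `t = 1`).
#' @return numeric vector of predicted weights, one per intake.
#' @examples
#' # geometric decay to 0 when intake is 0 and erf(beta) = 1/2
#' weight_trajectory(c(0, 0, 0), alpha = 1, beta = erfinv(0.5),
#'                   initial_weight = 10)
#' @export
weight_trajectory <- function(net_intake, alpha, beta, initial_weight,
                              mode = c("chained", "one_step_ahead"),
                              observed = NULL) {
  mode <- match.arg(mode)
  n <- length(net_intake)
  if (n < 1L) stop("'net_intake' must contain at least one week")
  if (mode == "one_step_ahead") {
    if (is.null(observed))
      stop("one-step-ahead simulation requires 'observed' weights")
    if (length(observed) != n)
      stop("'observed' must be aligned with 'net_intake'")
    prev <- c(initial_weight, observed[-n])
    return(weight_step(prev, net_intake, alpha, beta))
  }
  e <- erf(beta)
  out <- numeric(n)
  f <- initial_weight
  for (i in seq_len(n)) {
    f <- f * e + 7 * alpha * net_intake[i] * (1 - e)
    out[i] <- f
  }
  if (any(out <= 0))
    warning("trajectory reached non-positive weight; the recursion does not clamp")
  out
}

#' Fixed point of the weight recursion
#'
#' Under constant daily net intake `l` the chained recursion converges
#' geometrically (rate `erf(beta)`) to `7 * alpha * l`, independent of the
#' starting weight.
#'
#' @param alpha model constant (kg per kcal/day).
#' @param net_intake constant daily net intake (kcal/day).
#' @return steady-state weight (kg).
#' @export
steady_state_weight <- function(alpha, net_intake) 7 * alpha * net_intake

#' Coefficient of determination
#'
#' Goodness of fit between an observed and a predicted series.  The primary
#' definition is the coefficient of determination `1 - SSE/SST` (SST about
#' the observed mean), which can be negative for a fit worse than the mean;
#' `method = "correlation"` gives the squared Pearson correlation instead,
#' which is invariant to affine transformations of the prediction.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @param method `"determination"` (default) or `"correlation"`.
#' @return a number <= 1.
#' @export
r_squared <- function(observed, predicted,
                      method = c("determination", "correlation")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) stop("need at least two observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("'observed' values are all identical; R^2 undefined")
  if (method == "determination") {
    1 - sum((observed - predicted)^2) / sst
  } else {
    as.numeric(stats::cor(observed, predicted)^2)
  }
}
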