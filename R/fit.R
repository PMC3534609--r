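#' Fit the diffusion weight recursion to a weekly series
#'
#' Estimates the constants `(alpha, beta)` of the weekly recursion
#' `f(t) = f(t-1) erf(beta) + 7 alpha l(t) [1 - erf(beta)]` by minimizing
#' the sum of squared errors between the simulated trajectory and the
#' observed weights over a week window, using the iterative SCEM-UA global
#' optimizer ([iscem()]) on the corresponding log posterior
#' ([sse_log_posterior()]).  The window's predecessor week must be present
#' in the series to supply the initial weight.
#'
#' @param series a [weight_series()] (e.g. [minnesota_group()]).
#' @param window fitting window as `c(from, to)` week indices or a label
#'   spec such as `"S1:S24"` (closed interval).
#' @param config an [scem_config()]; `config$seed` controls all randomness.
#' @param lower,upper search bounds for `c(alpha, beta)`.  The defaults are
#'   a deliberately large box, `alpha` in (1e-6, 1\] and `beta` in
#'   (1e-6, 10\].
#' @param mode trajectory mode, `"chained"` (default) or
#'   `"one_step_ahead"`.
#' @return an object of class `"diffusion_fit"` with components `params`
#'   ([diffusion_params()]), `draws` (post-burn-in posterior samples),
#'   `fitted_trajectory`, `r2` and `r2_correlation`, `converged`, `window`,
#'   `mode`, `bounds_trace`, `gr_trace` and the input `series`.
#' @examples
#' \donttest{
#' fit <- diffusion_fit(minnesota_group(), "S1:S24",
#'                      config = scem_config(seed = 7))
#' coef(fit)
#' }
#' @export
diffusion_fit <- function(series, window = "S1:S24",
                          config = scem_config(),
                          lower = c(1e-6, 1e-6), upper = c(1, 10),
                          mode = c("chained", "one_step_ahead")) {
  stopifnot(inherits(series, "weight_series"))
  mode <- match.arg(mode)
  win <- parse_window(window)
  dat <- series_window(series, win[1], win[2])
  if (nrow(dat) != win[2] - win[1] + 1L)
    stop("fitting window has missing weeks in the series")
  w0 <- series$body_weight[series$week == win[1] - 1L]
  if (length(w0) != 1L)
    stop(sprintf("series must contain week %d (the window's predecessor) for the initial weight",
                 win[1] - 1L))
  log_post <- sse_log_posterior(dat$body_weight, dat$net_intake, w0,
                                mode = mode)
  opt <- iscem(log_post, lower, upper, config)
  params <- diffusion_params(opt$best$theta[1], opt$best$theta[2], w0)
  traj <- weight_trajectory(dat$net_intake, params$alpha, params$beta, w0,
                            mode = mode, observed = dat$body_weight)
  draws <- opt$draws
  colnames(draws) <- c("alpha", "beta", "log_density")
  structure(list(params = params, draws = draws,
                 fitted_trajectory = setNames(traj, dat$label),
                 r2 = r_squared(dat$body_weight, traj),
                 r2_correlation = r_squared(dat$body_weight, traj,
                                            method = "correlation"),
                 converged = opt$converged, window = win, mode = mode,
                 objective = "sse", bounds_trace = opt$bounds_trace,
                 gr_trace = opt$gr_trace, n_runs = opt$n_runs,
                 series = series, config = config, call = match.call()),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion weight-recursion fit, weeks S%d-S%d (%s)\n",
              x$window[1], x$window[2], x$mode))
  print(x$params)
  cat(sprintf("R^2 = %.5f (determination), %.5f (squared correlation)\n",
              x$r2, x$r2_correlation))
  cat(sprintf("optimizer: %d bound-refinement run(s), posterior run %s\n", x$n_runs,
              if (x$converged) "GR-converged" else "not GR-converged"))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(alpha = object$params$alpha, beta = object$params$beta)
}

#' @export
fitted.diffusion_fit <- function(object, ...) object$fitted_trajectory

#' @export
residuals.diffusion_fit <- function(object, ...) {
  dat <- series_window(object$series, object$window[1], object$window[2])
  setNames(dat$body_weight - object$fitted_trajectory, dat$label)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  qs <- apply(object$draws[, c("alpha", "beta"), drop = FALSE], 2,
              quantile, probs = c(0.025, 0.5, 0.975))
  out <- list(fit = object, posterior_quantiles = qs,
              n_draws = nrow(object$draws),
              sse = sum(residuals(object)^2))
  class(out) <- "summary.diffusion_fit"
  out
}

#' @export
print.summary.diffusion_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("SSE = %.5g over %d weeks; %d posterior draws\n", x$sse,
              length(x$fit$fitted_trajectory), x$n_draws))
  cat("posterior quantiles:\n")
  print(signif(x$posterior_quantiles, 6))
  invisible(x)
}

#' Simulate trajectories from the posterior of a fit
#'
#' Draws parameter vectors from the fit's posterior sample and replays the
#' chained recursion over the fitting window, giving the posterior spread
#' of the fitted trajectory.
#'
#' @param object a [diffusion_fit()].
#' @param nsim number of trajectories.
#' @param seed optional seed for the draw selection.
#' @param ... unused.
#' @return a matrix with `nsim` rows, one column per fitted week.
#' @export
simulate.diffusion_fit <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- series_window(object$series, object$window[1], object$window[2])
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  out <- t(vapply(idx, function(i) {
    suppressWarnings(
      weight_trajectory(dat$net_intake, object$draws[i, "alpha"],
                        object$draws[i, "beta"],
                        object$params$initial_weight))
  }, numeric(nrow(dat))))
  colnames(out) <- dat$label
  out
}

#' Plot observed and fitted weight trajectories
#'
#' @param x a [diffusion_fit()].
#' @param ... passed to [plot()].
#' @export
plot.diffusion_fit <- function(x, ...) {
  dat <- series_window(x$series, x$window[1], x$window[2])
  plot(dat$week, dat$body_weight, pch = 8,
       xlab = "week", ylab = "body weight (kg)",
       main = sprintf("weeks S%d-S%d: observed (*) vs model (o)",
                      x$window[1], x$window[2]), ...)
  points(dat$week, x$fitted_trajectory, pch = 1)
  lines(dat$week, x$fitted_trajectory, lty = 2)
  invisible(x)
}

#' Predict future weights from a fitted recursion
#'
#' Chains the recursion forward over a window that must immediately follow
#' the fitting window, starting by default from the last fitted week's
#' *observed* weight (`start = "fitted"` starts from the model's own last
#' fitted value instead).  A 95% interval per week is the percentile
#' envelope of trajectories replayed from the posterior draws, reported as
#' a half-width about the envelope centre; no observation-noise term is
#' added.
#'
#' @param object a [diffusion_fit()].
#' @param window prediction window (`c(from, to)` or `"S13:S24"`); must
#'   start at the week after the fitting window ends.
#' @param series series providing net intakes (and observed weights, if
#'   any) for the window; defaults to the fitting series.
#' @param start `"observed"` (default) or `"fitted"` start weight.
#' @param level interval coverage (default 0.95).
#' @param ... unused.
#' @return a data frame of class `"diffusion_pred"` with columns `week`,
#'   `label`, `predicted`, `ci_halfwidth`, `lower`, `upper` and `observed`
#'   (`NA` where unobserved); attributes `r2` (against available observed
#'   weights) and `start_weight`.
#' @export
predict.diffusion_fit <- function(object, window, series = object$series,
                                  start = c("observed", "fitted"),
                                  level = 0.95, ...) {
  start <- match.arg(start)
  win <- parse_window(window)
  if (win[1] != object$window[2] + 1L)
    stop(sprintf("prediction window must start at week %d (no gap after the fitted window)",
                 object$window[2] + 1L))
  dat <- series_window(series, win[1], win[2])
  if (nrow(dat) != win[2] - win[1] + 1L || anyNA(dat$net_intake))
    stop("net intakes for every prediction week are required")
  w_start <- if (start == "observed") {
    w <- object$series$body_weight[object$series$week == object$window[2]]
    if (length(w) != 1L)
      stop("observed start weight unavailable; use start = \"fitted\"")
    w
  } else {
    unname(object$fitted_trajectory[length(object$fitted_trajectory)])
  }
  pred <- weight_trajectory(dat$net_intake, object$params$alpha,
                            object$params$beta, w_start)
  a <- (1 - level) / 2
  draws <- object$draws
  env <- apply(draws, 1, function(d) {
    suppressWarnings(
      weight_trajectory(dat$net_intake, d["alpha"], d["beta"], w_start))
  })
  env <- matrix(env, nrow = nrow(dat))
  lo <- apply(env, 1, quantile, probs = a)
  hi <- apply(env, 1, quantile, probs = 1 - a)
  out <- data.frame(week = dat$week, label = dat$label, predicted = pred,
                    ci_halfwidth = (hi - lo) / 2, lower = lo, upper = hi,
                    observed = dat$body_weight)
  obs_ok <- is.finite(out$observed)
  attr(out, "r2") <- if (sum(obs_ok) >= 2)
    r_squared(out$observed[obs_ok], out$predicted[obs_ok]) else NA_real_
  attr(out, "start_weight") <- w_start
  attr(out, "start_source") <- start
  class(out) <- c("diffusion_pred", "data.frame")
  out
}

#' @export
print.diffusion_pred <- function(x, ...) {
  cat(sprintf("prediction %s-%s from start weight %.2f kg (%s); R^2 vs observed = %s\n",
              x$label[1], x$label[nrow(x)], attr(x, "start_weight"),
              attr(x, "start_source"),
              formatC(attr(x, "r2"), digits = 5, format = "f")))
  print.data.frame(x, digits = 5, ...)
  invisible(x)
}

#' Fit or apply the recursion to a single subject
#'
#' Per-subject trajectories use the group's net-intake schedule.  Because
#' subject baseline (week-0) weights were not published, the default
#' initial-weight policy back-solves the week-0 weight from the subject's
#' observed S1 weight by inverting one recursion step,
#' `f(0) = (f(1) - 7 alpha l(1) (1 - erf(beta))) / erf(beta)`; an explicit
#' numeric `initial_weight` overrides this.  When `params` is supplied the
#' constants are applied as given; otherwise they are fitted to the
#' subject's observed weights by [iscem()] (with the back-solve applied per
#' candidate, so the S1 residual is zero by construction).
#'
#' @param observed the subject's observed weekly weights (S1 onward, kg).
#' @param net_intake group daily net intakes aligned with `observed`.
#' @param params optional [diffusion_params()] or `c(alpha, beta)` to apply
#'   without fitting.
#' @param initial_weight `"backsolve"` (default) or an explicit week-0
#'   weight (kg).
#' @param config,lower,upper optimizer settings, as in [diffusion_fit()].
#' @return a list of class `"subject_fit"` with `params`, `trajectory`,
#'   `r2`, and (when fitted) `draws` and `converged`.
#' @export
subject_fit <- function(observed, net_intake, params = NULL,
                        initial_weight = "backsolve",
                        config = scem_config(),
                        lower = c(1e-6, 1e-6), upper = c(1, 10)) {
  stopifnot(length(observed) == length(net_intake), length(observed) >= 2)
  backsolve_w0 <- function(alpha, beta) {
    e <- erf(beta)
    if (e <= 0) stop("cannot back-solve the initial weight when erf(beta) = 0")
    (observed[1] - 7 * alpha * net_intake[1] * (1 - e)) / e
  }
  w0_for <- function(alpha, beta) {
    if (identical(initial_weight, "backsolve")) backsolve_w0(alpha, beta)
    else as.numeric(initial_weight)
  }
  if (!is.null(params)) {
    if (inherits(params, "diffusion_params")) {
      ab <- c(params$alpha, params$beta)
    } else ab <- as.numeric(params)[1:2]
    w0 <- w0_for(ab[1], ab[2])
    traj <- weight_trajectory(net_intake, ab[1], ab[2], w0)
    return(structure(list(params = diffusion_params(ab[1], ab[2], w0),
                          trajectory = traj,
                          r2 = r_squared(observed, traj),
                          fitted = FALSE),
                     class = "subject_fit"))
  }
  N <- length(observed)
  log_post <- function(theta) {
    w0 <- w0_for(theta[1], theta[2])
    pred <- suppressWarnings(
      weight_trajectory(net_intake, theta[1], theta[2], w0))
    -(N / 2) * log(max(sum((observed - pred)^2), 1e-300))
  }
  opt <- iscem(log_post, lower, upper, config)
  ab <- opt$best$theta
  w0 <- w0_for(ab[1], ab[2])
  traj <- weight_trajectory(net_intake, ab[1], ab[2], w0)
  structure(list(params = diffusion_params(ab[1], ab[2], w0),
                 trajectory = traj, r2 = r_squared(observed, traj),
                 draws = opt$draws, converged = opt$converged,
                 fitted = TRUE),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("subject-level recursion (%s): R^2 = %.4f\n",
              if (x$fitted) "fitted" else "applied", x$r2))
  print(x$params)
  invisible(x)
}
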