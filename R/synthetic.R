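#' Generate a synthetic weekly weight series
#'
#' Produces data with exactly the statistical structure the fitting
#' objective assumes: a deterministic latent trajectory from the chained
#' recursion, plus independent additive Gaussian noise on the *observed*
#' weights only (no process noise).  Intended for parameter-recovery and
#' coverage studies.
#'
#' Intake schedules: `"constant"` repeats `l0`; `"linear_ramp"` moves
#' linearly from `l0` to `l1`; `"minnesota_like"` linearly interpolates the
#' published group net-intake column onto `weeks` points, giving a
#' realistic semi-starvation covariate pattern.
#'
#' @param alpha,beta true recursion constants.
#' @param initial_weight true week-0 weight (kg).
#' @param weeks number of weeks (>= 2).
#' @param schedule intake schedule (see Details).
#' @param l0,l1 schedule levels (kcal/day); `l1` only for the ramp.
#' @param noise_sd standard deviation of the observation noise (kg), >= 0.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return a list with `series` (a [weight_series()] whose week 0 carries
#'   the initial weight), `latent` (the noise-free trajectory for weeks
#'   1..`weeks`) and `truth` (the generating [diffusion_params()]).
#' @examples
#' g <- synthetic_series(0.016337, 1.7096, 69.39, weeks = 24,
#'                       schedule = "minnesota_like", noise_sd = 0.3,
#'                       seed = 42)
#' head(g$series)
#' @export
synthetic_series <- function(alpha, beta, initial_weight, weeks = 24,
                             schedule = c("minnesota_like", "constant",
                                          "linear_ramp"),
                             l0 = 0, l1 = l0, noise_sd = 0.3, seed = 1L) {
  schedule <- match.arg(schedule)
  weeks <- as.integer(weeks)
  if (weeks < 2L) stop("'weeks' must be at least 2")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  net <- switch(schedule,
    constant = rep(l0, weeks),
    linear_ramp = seq(l0, l1, length.out = weeks),
    minnesota_like = {
      ref <- minnesota_group()
      src <- ref$net_intake[ref$week >= 1]
      stats::approx(seq_along(src), src,
                    xout = seq(1, length(src), length.out = weeks))$y
    })
  latent <- weight_trajectory(net, alpha, beta, initial_weight)
  set.seed(seed)
  observed <- latent + rnorm(weeks, 0, noise_sd)
  series <- weight_series(0:weeks,
                          body_weight = c(initial_weight, observed),
                          net_intake = c(NA_real_, net))
  list(series = series, latent = latent,
       truth = diffusion_params(alpha, beta, initial_weight))
}
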