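#' Sampler configuration for SCEM-UA
#'
#' Controls for the shuffled complex evolution Metropolis sampler and its
#' iterative bound-refinement wrapper.  Defaults follow common SCEM-UA
#' practice: population `s = 50` split into `q = 5` complexes, `L = s/q`
#' Metropolis steps per complex per shuffle, jump rate `2.4/sqrt(n)` for an
#' `n`-parameter posterior, density-ratio recentring threshold `1e6`,
#' minimum acceptance rate `0.1`, Gelman-Rubin threshold `1.2`, and the
#' first half of every sequence discarded as burn-in.
#'
#' @param n_pop population size `s`; must be a multiple of `n_complexes`
#'   and at least twice it.
#' @param n_complexes number of complexes (= parallel sequences) `q`.
#' @param n_steps Metropolis steps `L` per complex per shuffle; default
#'   `n_pop / n_complexes`.
#' @param density_ratio threshold `T`: when a sequence point's posterior
#'   density falls below the complex mean density by more than this factor,
#'   the proposal is recentred on the complex's best point.
#' @param min_acceptance `AR_min`: if a sequence's acceptance rate over a
#'   shuffle drops below this, its proposal covariance is halved.
#' @param jump_rate proposal scale `c_n`; default `2.4/sqrt(n)`, chosen at
#'   run time from the parameter dimension.
#' @param gr_threshold convergence when all potential-scale-reduction
#'   statistics fall below this (> 1).
#' @param max_shuffles cap on shuffle iterations of one SCEM-UA run.
#' @param min_shuffles shuffles to complete before convergence may be
#'   declared.  The Gelman-Rubin check is necessary but not sufficient:
#'   early chains still wandering over a huge box can agree in spread and
#'   pass it, so a substantial minimum sampling effort is enforced.
#' @param burn_in fraction of each sequence discarded before the
#'   Gelman-Rubin check and when returning posterior draws.
#' @param max_outer cap on outer bound-refinement iterations of [iscem()].
#' @param polish logical; refine the best draw returned by [iscem()] with a
#'   deterministic bounded simplex search (default `TRUE`).
#' @param epsilon relative tolerance on the log posterior density between
#'   successive SCEM-UA runs; the refinement loop stops when the best log
#'   densities of two consecutive runs agree to within
#'   `epsilon * max(1, |log p|)`.
#' @param seed integer seed; every run derives its random stream from it.
#' @return an object of class `"scem_config"`.
#' @export
scem_config <- function(n_pop = 50, n_complexes = 5, n_steps = NULL,
                        density_ratio = 1e6, min_acceptance = 0.1,
                        jump_rate = NULL, gr_threshold = 1.2,
                        max_shuffles = 300, min_shuffles = 150,
                        burn_in = 0.5, max_outer = 20, epsilon = 1e-6,
                        polish = TRUE, seed = 1L) {
  s <- as.integer(n_pop); q <- as.integer(n_complexes)
  if (s %% q != 0L) stop("'n_pop' must be divisible by 'n_complexes'")
  if (s < 2L * q) stop("'n_pop' must be at least twice 'n_complexes'")
  if (is.null(n_steps)) n_steps <- s %/% q
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  if (min_acceptance <= 0 || min_acceptance >= 1)
    stop("'min_acceptance' must be in (0, 1)")
  if (gr_threshold <= 1) stop("'gr_threshold' must exceed 1")
  if (burn_in <= 0 || burn_in >= 1) stop("'burn_in' must be in (0, 1)")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  structure(list(n_pop = s, n_complexes = q, n_steps = as.integer(n_steps),
                 density_ratio = density_ratio,
                 min_acceptance = min_acceptance, jump_rate = jump_rate,
                 gr_threshold = gr_threshold,
                 max_shuffles = as.integer(max_shuffles),
                 min_shuffles = as.integer(min_shuffles),
                 burn_in = burn_in, max_outer = as.integer(max_outer),
                 epsilon = epsilon, polish = isTRUE(polish),
                 seed = as.integer(seed)),
            class = "scem_config")
}

#' Rank pattern partitioning the population into complexes
#'
#' Complex `k` of `q` receives the density-ranked points
#' `q(j - 1) + k`, `j = 1..s/q`, so every complex spans the whole ranked
#' population.
#'
#' @param s population size.
#' @param q number of complexes; must divide `s`.
#' @return a list of `q` integer rank vectors.
#' @examples
#' partition_complexes(6, 2)  # ranks {1,3,5} and {2,4,6}
#' @export
partition_complexes <- function(s, q) {
  s <- as.integer(s); q <- as.integer(q)
  if (s %% q != 0L) stop("'s' must be divisible by 'q'")
  m <- s %/% q
  lapply(seq_len(q), function(k) seq(k, by = q, length.out = m))
}

#' Gelman-Rubin potential scale reduction
#'
#' For `q >= 2` chains of length `n` the statistic per parameter is
#' \deqn{\hat R = \sqrt{(n-1)/n + B/(nW)}}
#' with `W` the mean within-chain variance and `B` `n` times the variance
#' of the chain means.  When both `B` and `W` are zero (all chains constant
#' and equal) the statistic is defined as 1.  Values near 1 indicate
#' convergence.
#'
#' @param chains a list of numeric vectors (one parameter) or matrices with
#'   one row per draw and one column per parameter; all chains must have
#'   equal length.
#' @param burn_in fraction of each chain dropped from the front.
#' @return numeric vector of per-parameter statistics.
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(1, 2, 3)), burn_in = 0)  # sqrt(2/3)
#' @export
gelman_rubin <- function(chains, burn_in = 0) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  chains <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    keep <- seq.int(floor(nrow(ch) * burn_in) + 1L, nrow(ch))
    ch[keep, , drop = FALSE]
  })
  n <- nrow(chains[[1]])
  if (n < 2L) stop("need at least two post-burn-in draws per chain")
  if (!all(vapply(chains, nrow, 0L) == n)) stop("chains must have equal length")
  p <- ncol(chains[[1]])
  vapply(seq_len(p), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))  # n x q
    W <- mean(apply(draws, 2, var))
    B <- n * var(colMeans(draws))
    if (W <= 0) {
      if (B <= 0) return(1)
      return(Inf)
    }
    sqrt((n - 1) / n + B / (n * W))
  }, numeric(1))
}

# Draw s uniform points in the box, evaluate the log posterior, rank them.
# A posterior returning NaN is logged once and treated as -Inf.
init_population <- function(log_post, lower, upper, cfg) {
  n <- length(lower)
  theta <- matrix(runif(cfg$n_pop * n, rep(lower, each = cfg$n_pop),
                        rep(upper, each = cfg$n_pop)),
                  nrow = cfg$n_pop, ncol = n)
  lp <- apply(theta, 1, log_post)
  if (anyNA(lp)) {
    warning("posterior returned NaN; treated as log density -Inf")
    lp[is.na(lp)] <- -Inf
  }
  ord <- order(lp, decreasing = TRUE)
  list(theta = theta[ord, , drop = FALSE], lp = lp[ord])
}

# Cholesky factor of the complex covariance with a floor so proposals never
# degenerate to a point (floor tied to the box scale).
prop_chol <- function(theta_complex, lower, upper) {
  n <- ncol(theta_complex)
  sig <- cov(theta_complex)
  floor_sd <- 1e-8 * (upper - lower)
  diag(sig) <- pmax(diag(sig), floor_sd^2)
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) ch <- diag(sqrt(diag(sig)), n)
  ch
}

# One shuffle's worth of Metropolis evolution for a single complex/sequence.
# Returns updated complex, the L new sequence points, and the updated
# per-sequence proposal scale.
evolve_complex <- function(theta_c, lp_c, seq_cur, seq_lp, scale,
                           log_post, lower, upper, cfg, c_n) {
  L <- cfg$n_steps
  n <- ncol(theta_c)
  new_pts <- matrix(NA_real_, L, n)
  new_lp <- numeric(L)
  accepts <- 0L
  for (it in seq_len(L)) {
    ch <- prop_chol(theta_c, lower, upper)
    mean_lp <- mean(lp_c[is.finite(lp_c)])
    # recentre on the complex best when the sequence has drifted into a
    # region whose density is worse than the complex mean by factor > T
    centre <- if (is.finite(mean_lp) &&
                  (mean_lp - seq_lp) > log(cfg$density_ratio)) {
      theta_c[which.max(lp_c), ]
    } else seq_cur
    cand <- centre + (c_n * scale) * drop(rnorm(n) %*% ch)
    if (all(cand >= lower) && all(cand <= upper)) {
      lp_cand <- log_post(cand)
      if (is.na(lp_cand)) lp_cand <- -Inf
    } else {
      lp_cand <- -Inf  # outside the prior box: auto-reject
    }
    if (is.finite(lp_cand) &&
        (lp_cand >= seq_lp || log(runif(1)) < lp_cand - seq_lp)) {
      seq_cur <- cand; seq_lp <- lp_cand
      accepts <- accepts + 1L
      # accepted candidates enter the complex in place of a random member,
      # keeping it an (almost) unbiased rolling posterior sample; the best
      # member is protected so the complex maximum never decreases.
      # Replacing the *worst* member instead ratchets the population onto
      # an inner density contour and starves the proposal covariance.
      m <- nrow(theta_c)
      repl <- setdiff(seq_len(m), which.max(lp_c))
      repl <- repl[sample.int(length(repl), 1L)]
      theta_c[repl, ] <- cand
      lp_c[repl] <- lp_cand
    }
    new_pts[it, ] <- seq_cur
    new_lp[it] <- seq_lp
  }
  if (accepts / L < cfg$min_acceptance) scale <- scale / 2
  list(theta_c = theta_c, lp_c = lp_c, seq_cur = seq_cur, seq_lp = seq_lp,
       new_pts = new_pts, new_lp = new_lp, scale = scale)
}

#' Shuffled complex evolution Metropolis sampler
#'
#' Population MCMC global optimizer: `s` points are drawn uniformly in the
#' bounding box, ranked by posterior density and partitioned into `q`
#' interleaved complexes; each complex evolves a parallel Metropolis
#' sequence for `L` steps per shuffle, complexes are then unpacked,
#' re-ranked and re-partitioned, and the loop repeats until the
#' Gelman-Rubin statistic of every parameter falls below the threshold (or
#' `max_shuffles` is reached).
#'
#' @param log_post function mapping a parameter vector to the log posterior
#'   density (`-Inf` allowed; `NaN` is logged and treated as `-Inf`).
#' @param lower,upper numeric bound vectors (elementwise `lower < upper`);
#'   proposals outside the box are rejected.
#' @param config an [scem_config()].
#' @return a list of class `"scem_fit"`: `best` (list with `theta`,
#'   `log_density` — the highest-density point ever evaluated), `draws`
#'   (post-burn-in samples, one row per draw, with a `log_density` column),
#'   `sequences` (the q chains), `converged`, `gr_trace`, `n_shuffles` and
#'   `n_eval`.
#' @export
scem_ua <- function(log_post, lower, upper, config = scem_config()) {
  cfg <- config
  stopifnot(length(lower) == length(upper), all(lower < upper))
  n <- length(lower)
  c_n <- if (is.null(cfg$jump_rate)) 2.4 / sqrt(n) else cfg$jump_rate
  set.seed(cfg$seed)
  n_eval <- cfg$n_pop

  pop <- init_population(log_post, lower, upper, cfg)
  D_theta <- pop$theta; D_lp <- pop$lp
  q <- cfg$n_complexes
  # sequences start at the top-q ranked points
  seq_cur <- D_theta[seq_len(q), , drop = FALSE]
  seq_lp <- D_lp[seq_len(q)]
  chains <- lapply(seq_len(q), function(k)
    matrix(seq_cur[k, ], nrow = 1, ncol = n))
  chain_lp <- lapply(seq_len(q), function(k) seq_lp[k])
  scales <- rep(1, q)
  best <- list(theta = D_theta[1, ], log_density = D_lp[1])
  gr_trace <- list()
  converged <- FALSE
  shuffle <- 0L

  while (shuffle < cfg$max_shuffles) {
    shuffle <- shuffle + 1L
    parts <- partition_complexes(cfg$n_pop, q)
    for (k in seq_len(q)) {
      idx <- parts[[k]]
      ev <- evolve_complex(D_theta[idx, , drop = FALSE], D_lp[idx],
                           seq_cur[k, ], seq_lp[k], scales[k],
                           log_post, lower, upper, cfg, c_n)
      n_eval <- n_eval + cfg$n_steps
      D_theta[idx, ] <- ev$theta_c; D_lp[idx] <- ev$lp_c
      seq_cur[k, ] <- ev$seq_cur; seq_lp[k] <- ev$seq_lp
      chains[[k]] <- rbind(chains[[k]], ev$new_pts)
      chain_lp[[k]] <- c(chain_lp[[k]], ev$new_lp)
      scales[k] <- ev$scale
      if (ev$seq_lp > best$log_density)
        best <- list(theta = ev$seq_cur, log_density = ev$seq_lp)
    }
    kbest <- which.max(D_lp)
    if (D_lp[kbest] > best$log_density)
      best <- list(theta = D_theta[kbest, ], log_density = D_lp[kbest])
    ord <- order(D_lp, decreasing = TRUE)
    D_theta <- D_theta[ord, , drop = FALSE]; D_lp <- D_lp[ord]

    gr <- gelman_rubin(chains, burn_in = cfg$burn_in)
    gr_trace[[shuffle]] <- gr
    if (shuffle >= cfg$min_shuffles && all(is.finite(gr)) &&
        all(gr < cfg$gr_threshold)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("SCEM-UA did not reach GR < %.3g within %d shuffles",
                    cfg$gr_threshold, cfg$max_shuffles))

  draws <- do.call(rbind, lapply(seq_len(q), function(k) {
    keep <- seq.int(floor(nrow(chains[[k]]) * cfg$burn_in) + 1L,
                    nrow(chains[[k]]))
    cbind(chains[[k]][keep, , drop = FALSE], chain_lp[[k]][keep])
  }))
  colnames(draws) <- c(paste0("theta", seq_len(n)), "log_density")
  structure(list(best = best, draws = draws, sequences = chains,
                 converged = converged,
                 gr_trace = do.call(rbind, gr_trace),
                 n_shuffles = shuffle, n_eval = n_eval),
            class = "scem_fit")
}

# shift one bound vector toward theta, skipping coordinates whose update
# would invert the interval (repair rule; logged)
update_bounds <- function(lower, upper, theta, side) {
  if (side == "upper") {
    ok <- theta > lower + 1e-12 * pmax(1, abs(lower))
    if (!all(ok)) warning("bound update would invert interval; coordinate left unchanged")
    upper[ok] <- theta[ok]
  } else {
    ok <- theta < upper - 1e-12 * pmax(1, abs(upper))
    if (!all(ok)) warning("bound update would invert interval; coordinate left unchanged")
    lower[ok] <- theta[ok]
  }
  list(lower = lower, upper = upper)
}

#' Iterative SCEM-UA with bound refinement
#'
#' Wraps [scem_ua()] in the bound-refinement loop: run the sampler on a
#' deliberately large initial box and let the best point found be
#' `theta_o`; set the upper bound to `theta_o`; rerun, compare the best log
#' densities of consecutive runs, and keep shifting the upper (when the new
#' run is at least as good) or lower (when it is worse) bound to the newest
#' best point until two consecutive runs agree to within `epsilon`
#' (relative, on the log-density scale).  Bound updates are elementwise; an
#' update that would invert an interval leaves that coordinate unchanged.
#'
#' The returned point estimate is the posterior mode: the highest-density
#' draw seen across all runs, refined by a Nelder-Mead simplex search
#' constrained to the *initial* box (`polish = TRUE` in [scem_config()];
#' set it to `FALSE` to return the raw best draw).  Population MCMC
#' locates the global basin reliably but its best draw carries Monte-Carlo
#' jitter of the order of the posterior spread over the draw count; the
#' deterministic local step removes that jitter.
#'
#' @inheritParams scem_ua
#' @return a list of class `"iscem_fit"`: the `"scem_fit"` fields of the
#'   first run (whose box is the full prior support, so its draws are an
#'   untruncated posterior sample), with `best` replaced by the
#'   highest-density point seen across all refinement runs, plus
#'   `bounds_trace` (one row per run: bounds used and best log density) and
#'   `n_runs`.
#' @export
iscem <- function(log_post, lower, upper, config = scem_config()) {
  cfg <- config
  run_cfg <- cfg
  run_cfg$seed <- cfg$seed
  res_o <- scem_ua(log_post, lower, upper, run_cfg)
  p_o <- res_o$best$log_density
  trace <- list(c(lower, upper, p_o))
  best_overall <- res_o$best
  b <- update_bounds(lower, upper, res_o$best$theta, "upper")
  res_w <- res_o
  for (run in 2:max(2L, cfg$max_outer)) {
    run_cfg$seed <- cfg$seed + (run - 1L) * 1009L
    res_w <- scem_ua(log_post, b$lower, b$upper, run_cfg)
    p_w <- res_w$best$log_density
    trace[[run]] <- c(b$lower, b$upper, p_w)
    if (p_w > best_overall$log_density) best_overall <- res_w$best
    if (abs(p_o - p_w) <= cfg$epsilon * max(1, abs(p_o))) break
    side <- if (p_o <= p_w) "upper" else "lower"
    b <- update_bounds(b$lower, b$upper, res_w$best$theta, side)
    p_o <- p_w
    if (run == cfg$max_outer)
      warning("bound-refinement loop hit 'max_outer' before converging")
  }
  if (isTRUE(cfg$polish)) {
    neg <- function(th) {
      if (any(th < lower) || any(th > upper)) return(1e300)
      lp <- log_post(th)
      if (!is.finite(lp)) 1e300 else -lp
    }
    pol <- stats::optim(best_overall$theta, neg, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    pol <- stats::optim(pol$par, neg, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (-pol$value > best_overall$log_density)
      best_overall <- list(theta = pol$par, log_density = -pol$value)
  }
  n <- length(lower)
  tr <- do.call(rbind, trace)
  colnames(tr) <- c(paste0("lower", seq_len(n)), paste0("upper", seq_len(n)),
                    "best_log_density")
  # Posterior inference (draws, chains, convergence diagnostics) comes from
  # the FIRST run, whose box is the full prior support; the refined boxes of
  # later runs serve optimization only and would truncate the posterior.
  out <- res_o
  out$best <- best_overall  # highest-density point over all refinement runs
  out$bounds_trace <- tr
  out$n_runs <- nrow(tr)
  class(out) <- c("iscem_fit", "scem_fit")
  out
}

#' Log posterior for least-squares trajectory fitting
#'
#' Box-Tiao noninformative form for a Gaussian error model with unknown
#' variance: `log p(theta | y) = -(N/2) log SSE(theta)` up to a constant,
#' so maximizing the posterior density is exactly minimizing the sum of
#' squared errors between the simulated and observed trajectories.
#'
#' @param observed observed weekly weights over the fitting window (kg).
#' @param net_intake daily net intakes aligned with `observed` (kcal/day).
#' @param initial_weight weight at the window's predecessor week (kg).
#' @param mode trajectory mode passed to [weight_trajectory()].
#' @return a function mapping `c(alpha, beta)` to the log posterior.
#' @export
sse_log_posterior <- function(observed, net_intake, initial_weight,
                              mode = c("chained", "one_step_ahead")) {
  mode <- match.arg(mode)
  N <- length(observed)
  force(net_intake); force(initial_weight)
  function(theta) {
    pred <- suppressWarnings(
      weight_trajectory(net_intake, theta[1], theta[2], initial_weight,
                        mode = mode, observed = observed))
    sse <- sum((observed - pred)^2)
    -(N / 2) * log(max(sse, 1e-300))
  }
}
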