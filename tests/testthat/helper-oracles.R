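# Independent oracles, deliberately not sharing code paths with the package.

# erf by its Maclaurin series, erf(x) = (2/sqrt(pi)) sum (-1)^n x^(2n+1)/(n!(2n+1)).
# Converges for all x; accurate to ~1e-13 for |x| <= 3, ample for test tolerances.
erf_series <- function(x) {
  vapply(x, function(xi) {
    term <- xi
    total <- xi
    for (n in 1:80) {
      term <- -term * xi^2 / n
      total <- total + term / (2 * n + 1)
    }
    2 / sqrt(pi) * total
  }, numeric(1))
}

# hand recursion oracle for the weekly model (plain loop, no vectorization)
recursion_oracle <- function(net, alpha, beta, w0) {
  e <- erf_series(beta)
  out <- numeric(length(net))
  f <- w0
  for (i in seq_along(net)) {
    f <- f * e + 7 * alpha * net[i] * (1 - e)
    out[i] <- f
  }
  out
}

# group fixture slices used across tests
group_weights <- function() {
  g <- minnesota_group()
  list(w0 = g$body_weight[g$week == 0],
       obs = g$body_weight[g$week >= 1],
       net = g$net_intake[g$week >= 1])
}

# light optimizer settings for tests that fit many times
light_config <- function(seed, ...) {
  scem_config(seed = seed, min_shuffles = 30, max_shuffles = 60,
              max_outer = 2, epsilon = 1e-2, ...)
}
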