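test_that("published constants reproduce the printed goodness of fit", {
  gw <- group_weights()
  # full-window fit: chained mode + coefficient of determination matches;
  # the one-step-ahead and squared-correlation variants do not
  tr <- weight_trajectory(gw$net, 0.016337, 1.7096, gw$w0)
  expect_lt(abs(r_squared(gw$obs, tr) - 0.99666), 1e-4)
  osa <- weight_trajectory(gw$net, 0.016337, 1.7096, gw$w0,
                           mode = "one_step_ahead", observed = gw$obs)
  expect_gt(abs(r_squared(gw$obs, osa) - 0.99666), 1e-4)
  expect_gt(abs(r_squared(gw$obs, tr, method = "correlation") - 0.99666), 1e-4)
  # validation window with its own constants
  tr12 <- weight_trajectory(gw$net[1:12], 0.0170757, 1.7029, gw$w0)
  expect_equal(r_squared(gw$obs[1:12], tr12), 0.98499, tolerance = 0.001 / 0.98)
})

test_that("fitting recovers known constants exactly from noiseless data", {
  syn <- synthetic_series(0.016337, 1.7096, 69.39, weeks = 24,
                          schedule = "minnesota_like", noise_sd = 0, seed = 11)
  fit <- suppressWarnings(diffusion_fit(syn$series, c(1, 24),
                                        config = light_config(11)))
  expect_lt(max(abs(coef(fit) - c(0.016337, 1.7096)) / c(0.016337, 1.7096)),
            1e-4)
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("fit objects expose coherent accessors and methods", {
  syn <- synthetic_series(0.016, 1.7, 70, weeks = 12,
                          schedule = "constant", l0 = -150,
                          noise_sd = 0.2, seed = 21)
  fit <- suppressWarnings(diffusion_fit(syn$series, c(1, 12),
                                        config = light_config(21)))
  expect_s3_class(fit, "diffusion_fit")
  expect_named(coef(fit), c("alpha", "beta"))
  expect_length(fitted(fit), 12)
  obs <- syn$series$body_weight[syn$series$week >= 1]
  expect_equal(unname(fitted(fit) + residuals(fit)), obs)
  expect_equal(fit$r2, r_squared(obs, unname(fitted(fit))))
  s <- summary(fit)
  expect_s3_class(s, "summary.diffusion_fit")
  expect_equal(unname(s$sse), sum(residuals(fit)^2))
  sims <- simulate(fit, nsim = 7, seed = 1)
  expect_equal(dim(sims), c(7, 12))
  expect_output(print(fit), "R\\^2")
})

test_that("fitting demands the window's predecessor week", {
  syn <- synthetic_series(0.016, 1.7, 70, weeks = 10, schedule = "constant",
                          l0 = 100, noise_sd = 0, seed = 3)
  s <- syn$series[syn$series$week >= 1, ]
  class(s) <- c("weight_series", "data.frame")
  expect_error(diffusion_fit(s, c(1, 10), config = light_config(3)),
               "week 0")
  s2 <- s[s$week != 1, ]
  class(s2) <- c("weight_series", "data.frame")
  expect_error(diffusion_fit(s2, c(2, 10), config = light_config(3)),
               "week 1")
})

test_that("prediction requires an abutting window and reports uncertainty", {
  syn <- synthetic_series(0.016, 1.71, 70, weeks = 24,
                          schedule = "minnesota_like", noise_sd = 0.2, seed = 31)
  fit <- suppressWarnings(diffusion_fit(syn$series, c(1, 12),
                                        config = light_config(31)))
  expect_error(predict(fit, c(14, 24)), "gap")
  pred <- predict(fit, c(13, 24))
  expect_s3_class(pred, "diffusion_pred")
  expect_equal(nrow(pred), 12)
  expect_true(all(pred$ci_halfwidth >= 0))
  expect_true(all(pred$lower <= pred$predicted + 1e-9))
  expect_true(all(pred$upper >= pred$predicted - 1e-9))
  # default start is the last fitted week's observed weight
  w12 <- syn$series$body_weight[syn$series$week == 12]
  expect_equal(attr(pred, "start_weight"), w12)
  first <- weight_step(w12, syn$series$net_intake[syn$series$week == 13],
                       coef(fit)["alpha"], coef(fit)["beta"])
  expect_equal(pred$predicted[1], unname(first))
  # fitted-start flag uses the model's own last fitted value
  pred2 <- predict(fit, c(13, 24), start = "fitted")
  expect_equal(attr(pred2, "start_weight"),
               unname(fitted(fit)[12]))
  expect_equal(attr(pred, "r2"),
               r_squared(pred$observed, pred$predicted))
})

test_that("a collapsed posterior yields zero interval width", {
  syn <- synthetic_series(0.016, 1.71, 70, weeks = 16,
                          schedule = "minnesota_like", noise_sd = 0.1, seed = 41)
  fit <- suppressWarnings(diffusion_fit(syn$series, c(1, 8),
                                        config = light_config(41)))
  fit$draws <- fit$draws[rep(1, 50), ]
  pred <- predict(fit, c(9, 16))
  expect_true(all(pred$ci_halfwidth == 0))
})

test_that("interval widths shrink as the posterior concentrates", {
  # temper the posterior by duplicating draws nearest the mode
  syn <- synthetic_series(0.016, 1.71, 70, weeks = 24,
                          schedule = "minnesota_like", noise_sd = 0.3, seed = 51)
  fit <- suppressWarnings(diffusion_fit(syn$series, c(1, 12),
                                        config = light_config(51)))
  wide <- predict(fit, c(13, 24))
  keep <- order(fit$draws[, "log_density"], decreasing = TRUE)
  fit$draws <- fit$draws[keep[seq_len(max(2, nrow(fit$draws) %/% 20))], ,
                         drop = FALSE]
  narrow <- predict(fit, c(13, 24))
  expect_lt(mean(narrow$ci_halfwidth), mean(wide$ci_halfwidth) + 1e-12)
})

test_that("per-subject application reproduces printed subject-level fits", {
  subs <- minnesota_subjects()
  gw <- group_weights()
  # the printed model rows themselves score the printed R^2
  s109 <- subs[["109"]]
  expect_equal(r_squared(s109$observed, s109$model), 0.996, tolerance = 0.001)
  s122 <- subs[["122"]]
  expect_equal(r_squared(s122$observed, s122$model), 0.891, tolerance = 0.001)
  # observed identical to the model rows gives a perfect fit
  expect_equal(r_squared(s109$model, s109$model), 1)
})

test_that("subject back-solve recovers the starting weight on synthetic data", {
  gw <- group_weights()
  truth <- c(alpha = 0.0165, beta = 1.72)
  latent <- weight_trajectory(gw$net, truth["alpha"], truth["beta"], 68.2)
  sf <- subject_fit(latent, gw$net, params = truth)
  expect_equal(sf$params$initial_weight, 68.2, tolerance = 1e-9)
  expect_equal(sf$r2, 1, tolerance = 1e-12)
  # fitted variant: back-solved start makes the S1 residual vanish
  set.seed(61)
  obs <- latent + rnorm(24, 0, 0.05)
  sf2 <- suppressWarnings(subject_fit(obs, gw$net, config = light_config(61)))
  expect_equal(sf2$trajectory[1], obs[1], tolerance = 1e-9)
  expect_gt(sf2$r2, 0.98)
})
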