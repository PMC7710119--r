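# Training loop: end-to-end recovery on a closed-form system, determinism,
# staging behaviour, and the fitted-object methods.

toy_system <- function() {
  ode_system("toy", "x", "rate", 1.0, 1, c(0, 3), 1,
             function(x, t, p) -p[1] * x, 1,
             jacobian = function(x, t, p)
               list(Jx = matrix(-p[1], 1, 1), Jp = matrix(-x[1], 1, 1)))
}

toy_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      toy <- toy_system()
      dat <- make_dataset(toy, n = 50, noise_level = 0, seed = 1)
      cfg <- sbinn_config(depth = 2, width = 16,
                          features = c("t", "exp(-t)"), t_scale = 3,
                          output_scales = 1)
      fit <<- sbinn(toy, dat, config = cfg,
                    schedule = sbinn_schedule(500, 3000, n_ode = 100,
                                              log_every = 500),
                    seed = 2)
    }
    fit
  }
})

test_that("an unknown decay rate is recovered within 1% from noiseless data", {
  fit <- toy_fit()
  expect_lt(abs(coef(fit)[["rate"]] - 1.0), 0.01)
})

test_that("the fitted surrogate reproduces observations and hidden dynamics", {
  fit <- toy_fit()
  obs <- fit$data$observations
  # noiseless fit: prediction ~ observation at the observation times
  expect_lt(max(abs(fitted(fit) - obs$values)), 0.01)
  expect_equal(unname(residuals(fit)), unname(obs$values - fitted(fit)))
  # full trajectory close to the closed form
  tq <- seq(0, 3, length.out = 50)
  expect_lt(max(abs(predict(fit, tq)[, 1] - exp(-tq))), 0.01)
  expect_warning(predict(fit, 5), "extrapolation")
})

test_that("training is bit-reproducible under a fixed seed", {
  toy <- toy_system()
  dat <- make_dataset(toy, n = 20, noise_level = 0.05, seed = 3)
  cfg <- sbinn_config(depth = 2, width = 8, features = c("t", "exp(-t)"),
                      t_scale = 3, output_scales = 1)
  sch <- sbinn_schedule(100, 100, n_ode = 40, log_every = 50)
  f1 <- sbinn(toy, dat, config = cfg, schedule = sch, seed = 7)
  f2 <- sbinn(toy, dat, config = cfg, schedule = sch, seed = 7)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$history, f2$history)
  f3 <- sbinn(toy, dat, config = cfg, schedule = sch, seed = 8)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("supervised-only training decreases the data loss in trend", {
  toy <- toy_system()
  dat <- make_dataset(toy, n = 30, noise_level = 0, seed = 5)
  cfg <- sbinn_config(depth = 2, width = 8, features = c("t", "exp(-t)"),
                      t_scale = 3, output_scales = 1)
  fit <- sbinn(toy, dat, config = cfg,
               schedule = sbinn_schedule(2000, 0, n_ode = 10,
                                         log_every = 200), seed = 1)
  trace <- fit$history[, "data"]
  # smoothed trend decreases over the stage
  expect_lt(mean(tail(trace, 3)), mean(head(trace, 3)))
  # stage-2 losses were never evaluated
  expect_true(all(fit$history[, "stage"] == 1))
})

test_that("stage counts of zero skip stages; loss history records both", {
  toy <- toy_system()
  dat <- make_dataset(toy, n = 20, noise_level = 0, seed = 4)
  cfg <- sbinn_config(depth = 2, width = 8, features = c("t", "exp(-t)"),
                      t_scale = 3, output_scales = 1)
  fit <- sbinn(toy, dat, config = cfg,
               schedule = sbinn_schedule(0, 200, n_ode = 20,
                                         log_every = 100), seed = 1)
  expect_true(all(fit$history[, "stage"] == 2))
})

test_that("the summary table reports relative errors against targets", {
  fit <- toy_fit()
  s <- summary(fit)
  expect_equal(s$table$target, 1.0)
  expect_equal(s$table$rel_error,
               abs(s$table$inferred - s$table$target) / s$table$target)
  expect_output(print(s), "rel_error")
  expect_output(print(fit), "inferred parameters")
})

test_that("auto-balance freezes reciprocal-magnitude weights at stage two", {
  toy <- toy_system()
  dat <- make_dataset(toy, n = 20, noise_level = 0.1, seed = 6)
  cfg <- sbinn_config(depth = 2, width = 8, features = c("t", "exp(-t)"),
                      t_scale = 3, output_scales = 1)
  fit <- sbinn(toy, dat, config = cfg, auto_balance = TRUE,
               schedule = sbinn_schedule(200, 200, n_ode = 30,
                                         log_every = 100), seed = 1)
  # weights were rescaled away from the all-ones default
  expect_false(all(fit$weights$data == 1))
  expect_true(all(unlist(fit$weights) > 0))
})

test_that("forecasting integrates the ODE with the inferred parameters", {
  fit <- toy_fit()
  fc <- forecast(fit, times = seq(0, 4, length.out = 9))
  # with p ~ 1 recovered, the forecast tracks e^{-t} beyond the window
  expect_equal(unname(fc[, "x"]), exp(-fc[, "time"] * coef(fit)[[1]]),
               tolerance = 1e-6)
})
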