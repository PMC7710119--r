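# Benchmark right-hand sides: closed-form behaviour, independent oracles,
# analytic Jacobians, and the nutrition driver.

test_that("glycolysis rhs matches its structure and a hand-coded oracle", {
  sys <- glycolysis_model()
  x <- sys$x0
  # all rates zero (Hill constants kept valid): every term carries a rate
  pz <- rep(0, 14); pz[10] <- 4; pz[11] <- 0.52
  expect_equal(sys$rhs(x, 0, pz), rep(0, 7))
  # constant influx only: dS1/dt = J0, all other components zero
  p0 <- pz; p0[1] <- 2.5
  expect_equal(sys$rhs(x, 0, p0), c(2.5, rep(0, 6)))
  # term-by-term hand evaluation at nominal values and random states
  set.seed(1)
  for (i in 1:20) {
    xr <- runif(7, 0.01, 3)
    expect_equal(sys$rhs(xr, 0, sys$p_nominal),
                 glycolysis_hand_oracle(xr, as.numeric(sys$p_nominal)),
                 tolerance = 1e-12)
  }
  expect_error(sys$rhs(c(NA, x[-1]), 0, sys$p_nominal), "finite")
  p_bad <- sys$p_nominal; p_bad["K1"] <- 0
  expect_error(sys$rhs(x, 0, p_bad), "K1")
})

test_that("apoptosis rhs equals the stoichiometry-times-flux oracle exactly", {
  sys <- apoptosis_model()
  expect_equal(sys$rhs(sys$x0, 0, rep(0, 9)), rep(0, 8))
  set.seed(42)
  for (i in 1:100) {
    x <- runif(8, 0, 1e5)
    p <- runif(9, 1e-9, 1e-1)
    expect_equal(sys$rhs(x, 0, p), apoptosis_stoich_oracle(x, p),
                 tolerance = 1e-13)
  }
  expect_error(sys$rhs(sys$x0, 0, rep(1e-3, 5)), "length 9")
  expect_warning(sys$rhs(c(-50, sys$x0[-1]), 0, sys$p_nominal), "negative")
})

test_that("survival and death scenarios differ only in the inhibitor level", {
  surv <- apoptosis_model(x7_0 = 2.9e4)
  death <- apoptosis_model(x7_0 = 2.9e3)
  expect_equal(surv$x0[["x7"]], 2.9e4)
  expect_equal(death$x0[["x7"]], 2.9e3)
  expect_equal(surv$x0[-7], death$x0[-7])
  # phenotypes: effector caspase stays low under high inhibitor, escapes
  # under low inhibitor
  t_grid <- seq(0, 60, by = 1)
  x4s <- solve_reference(surv, times = t_grid)[, "x4"]
  x4d <- solve_reference(death, times = t_grid)[, "x4"]
  expect_lt(max(x4s), 10)
  expect_gt(max(x4d), 1e5)
})

test_that("ultradian rhs: equilibrium, filter chain and meal forcing", {
  sys0 <- ultradian_model(schedule = nutrition_schedule(numeric(0),
                                                        numeric(0)))
  # frozen initial state is the autonomous fixed point
  expect_lt(max(abs(sys0$rhs(sys0$x0, 0, sys0$p_nominal))), 1e-6)
  # filter chain: dh1/dt = 0 when h1 equals Ip
  x <- sys0$x0; x[4] <- x[1]
  expect_equal(sys0$rhs(x, 0, sys0$p_nominal)[4], 0)
  # with Ip frozen, h1..h3 all converge to Ip (three-stage filter property)
  p <- sys0$p_nominal
  filt <- function(t, y, parms) {
    ip <- 77
    td <- parms[["td"]]
    list(c((ip - y[1]) / td, (y[1] - y[2]) / td, (y[2] - y[3]) / td))
  }
  out <- deSolve::ode(c(0, 0, 0), c(0, 500), filt, p)
  expect_equal(unname(out[2, 2:4]), rep(77, 3), tolerance = 1e-3)
  expect_error(
    ultradian_model()$rhs(x, 0, replace(p, "td", -1)), "td")
  # meal forcing raises dG/dt by 1000 mg/g times the driver
  sys <- ultradian_model()
  f_before <- sys$rhs(sys$x0, 299.9, p)
  f_after <- sys$rhs(sys$x0, 300.0, p)
  jump <- f_after[3] - f_before[3]
  expect_equal(jump,
               1000 * nutrition_driver(300, sys$schedule) -
               1000 * nutrition_driver(299.9, sys$schedule),
               tolerance = 1e-6)
})

test_that("nutrition driver follows the closed form and conserves mass", {
  sched <- nutrition_schedule(300, 60, decay = 0.0083)
  expect_equal(nutrition_driver(0, sched), 0)
  expect_equal(nutrition_driver(299.999, sched), 0)
  expect_equal(nutrition_driver(300, sched), 60 * 0.0083)
  expect_equal(nutrition_driver(300 + 1 / 0.0083, sched),
               60 * 0.0083 / exp(1))
  # benchmark three-meal schedule is the default
  bench <- nutrition_schedule()
  expect_equal(bench$times, c(300, 650, 1100))
  expect_equal(bench$masses, c(60, 40, 50))
  # absorbed mass: integral over [t_j, Inf) equals m_j
  mass <- stats::integrate(function(t) nutrition_driver(t, sched), 300, Inf,
                           rel.tol = 1e-9)$value
  expect_equal(mass, 60, tolerance = 1e-6)
  expect_true(all(nutrition_driver(seq(0, 2000, by = 7), bench) >= 0))
  expect_error(nutrition_schedule(c(650, 300), c(40, 60)), "sorted")
})

test_that("analytic Jacobians agree with finite differences on all models", {
  set.seed(5)
  for (nm in c("glycolysis", "apoptosis", "ultradian")) {
    sys <- get_model(nm)
    p <- sys$p_nominal
    x <- abs(sys$x0 * (1 + runif(sys$S, -0.3, 0.3))) + 0.01
    t <- runif(1, 10, 50)
    J <- sys$jacobian(x, t, p)
    h <- 1e-6
    Jx_fd <- vapply(seq_len(sys$S), function(i) {
      dx <- max(abs(x[i]) * h, 1e-10)
      xp <- x; xm <- x; xp[i] <- x[i] + dx; xm[i] <- x[i] - dx
      (sys$rhs(xp, t, p) - sys$rhs(xm, t, p)) / (2 * dx)
    }, numeric(sys$S))
    expect_lt(max(abs(J$Jx - Jx_fd)) / max(abs(J$Jx)), 1e-5)
    Jp_fd <- vapply(seq_len(sys$K), function(k) {
      dp <- max(abs(p[k]) * h, 1e-12)
      pp <- p; pm <- p; pp[k] <- p[k] + dp; pm[k] <- p[k] - dp
      (sys$rhs(x, t, pp) - sys$rhs(x, t, pm)) / (2 * dp)
    }, numeric(sys$S))
    # relative error with a scale floor: entries of wildly different sizes
    scale <- max(abs(J$Jp))
    expect_lt(max(abs(J$Jp - Jp_fd)) / scale, 1e-5)
  }
})

test_that("ode_system validates its invariants", {
  expect_error(ode_system("bad", c("a", "b"), "p", 1, c(1, 2), c(0, 10),
                          c(2, 1), function(x, t, p) c(0, 0), c(1, 1)),
               "strictly increasing")
  expect_error(ode_system("bad", "a", "p", 1, 1, c(0, 10), 1,
                          function(x, t, p) NaN, 1), "finite")
  reg <- get_model("glycolysis")
  expect_s3_class(reg, "ode_system")
  expect_equal(reg$name, "glycolysis")
})
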