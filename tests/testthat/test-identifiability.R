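# Fisher-information toolkit: closed forms, scaling laws, invariances and
# null-space analysis.

test_that("sensitivities match the closed form for exponential decay", {
  decay <- ode_system("decay", "x", "rate", 1.4, 1, c(0, 5), 1,
                      function(x, t, p) -p[1] * x, 1,
                      jacobian = function(x, t, p)
                        list(Jx = matrix(-p[1], 1, 1),
                             Jp = matrix(-x[1], 1, 1)))
  times <- seq(0.5, 4.5, by = 0.5)
  s <- output_sensitivities(decay, times = times)
  # dx/dp at time t is -t e^{-pt}
  expect_equal(as.numeric(s), -times * exp(-1.4 * times), tolerance = 1e-6)
})

test_that("a parameter the system does not depend on has zero sensitivity", {
  sys <- ode_system("partial", "x", c("used", "unused"), c(0.5, 3), 1,
                    c(0, 4), 1, function(x, t, p) -p[1] * x, 1,
                    jacobian = function(x, t, p)
                      list(Jx = matrix(-p[1], 1, 1),
                           Jp = matrix(c(-x[1], 0), 1, 2)))
  s <- output_sensitivities(sys, times = c(1, 2, 3))
  expect_equal(unname(s[, "unused"]), rep(0, 3))
  expect_false(any(s[, "used"] == 0))
})

test_that("sensitivity ODE agrees with finite differences on the glycolysis
           design", {
  sys <- glycolysis_model()
  times <- sample_observation_times(40, c(0, 10), seed = 8)
  s <- output_sensitivities(sys, times = times, rtol = 1e-10, atol = 1e-10)
  p <- sys$p_nominal
  h <- 1e-5
  for (k in c(1, 6, 10, 13)) {   # spot-check a spread of parameters
    pp <- p; pm <- p
    pp[k] <- p[k] * (1 + h); pm[k] <- p[k] * (1 - h)
    grid <- sort(unique(c(0, times)))
    up <- solve_reference(sys, pp, grid, rtol = 1e-10,
                          atol = 1e-12)[match(times, grid), 6:7]
    dn <- solve_reference(sys, pm, grid, rtol = 1e-10,
                          atol = 1e-12)[match(times, grid), 6:7]
    fd <- as.numeric((up - dn) / (2 * p[k] * h))
    expect_lt(max(abs(s[, k] - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("FIM closed form, scaling law and additivity", {
  # y = p * t observed at times t_n with noise sigma: F = sum t_n^2 / sigma^2
  lin <- ode_system("lin", "x", "slope", 2, 0, c(0, 10), 1,
                    function(x, t, p) p[1], 1,
                    jacobian = function(x, t, p)
                      list(Jx = matrix(0, 1, 1), Jp = matrix(1, 1, 1)))
  times <- c(1, 2, 4, 7)
  s <- output_sensitivities(lin, times = times)
  expect_equal(as.numeric(s), times, tolerance = 1e-8)
  F <- fisher_information(s, noise_stds = 0.5)
  expect_equal(F[1, 1], sum(times^2) / 0.25, tolerance = 1e-7)
  # doubling sigma divides F by 4
  F2 <- fisher_information(s, noise_stds = 1)
  expect_equal(F2[1, 1], F[1, 1] / 4)
  # additivity over independent blocks
  sa <- s[1:2, , drop = FALSE]; attr(sa, "n_times") <- 2
  sb <- s[3:4, , drop = FALSE]; attr(sb, "n_times") <- 2
  expect_equal(fisher_information(sa, 0.5) + fisher_information(sb, 0.5), F)
  expect_error(fisher_information(s, 0), "positive")
  # Cramer-Rao closed form: sigma_p = sigma / sqrt(sum t_n^2)
  expect_equal(as.numeric(crb_stddev(F)), 0.5 / sqrt(sum(times^2)),
               tolerance = 1e-10)
})

test_that("crb_stddev handles diagonal and scaled problems", {
  F <- diag(c(4, 25, 1e4))
  dimnames(F) <- list(letters[1:3], letters[1:3])
  expect_equal(as.numeric(crb_stddev(F)), c(0.5, 0.2, 0.01))
  a <- 3.7
  expect_equal(as.numeric(crb_stddev(a * F)),
               as.numeric(crb_stddev(F)) / sqrt(a))
})

test_that("correlation matrix: identity for diagonal F, perfect correlation
           for duplicated sensitivities", {
  F <- diag(c(2, 3, 4))
  expect_equal(correlation_matrix(F), diag(3))
  # two identical sensitivity columns -> |R| = 1 for the pair
  set.seed(2)
  s <- cbind(rnorm(30), rnorm(30), rnorm(30))
  s <- cbind(s, s[, 3])
  attr(s, "n_times") <- 30
  F <- fisher_information(s, 1)
  R <- correlation_matrix(F)
  expect_equal(abs(R[3, 4]), 1, tolerance = 1e-6)
})

test_that("null-eigenvector analysis on constructed matrices", {
  # full-rank: no null vectors
  expect_length(null_eigenvectors(diag(c(1, 2, 3)))$dominant, 0)
  # rank-1 F = vv': two null vectors orthogonal to v
  v <- c(2, 1, -1)
  F <- tcrossprod(v)
  nv <- null_eigenvectors(F)
  expect_equal(ncol(nv$vectors), 2)
  expect_lt(max(abs(t(nv$vectors) %*% v)), 1e-10)
  expect_equal(colSums(nv$vectors^2), rep(1, 2), tolerance = 1e-12)
  # dominant component: construct a null direction along one axis
  F2 <- diag(c(1, 1e-14, 1))
  nv2 <- null_eigenvectors(F2, rel_tol = 1e-10)
  expect_equal(nv2$dominant, 2L)
})

test_that("FIM is invariant to observation order and consistent under
           parameter permutation", {
  sys <- glycolysis_model()
  times <- sample_observation_times(30, c(0, 10), seed = 4)
  s <- output_sensitivities(sys, times = times)
  F <- fisher_information(s, c(0.01, 0.1))
  # permute observation rows within each observable block
  n <- length(times)
  set.seed(1); perm <- sample(n)
  s2 <- rbind(s[perm, ], s[n + perm, ])
  attr(s2, "n_times") <- n
  F2 <- fisher_information(s2, c(0.01, 0.1))
  expect_equal(unname(F), unname(F2), tolerance = 1e-12)
  # permuting parameter columns permutes F rows/columns consistently
  pp <- sample(ncol(s))
  s3 <- s[, pp]; attr(s3, "n_times") <- n
  F3 <- fisher_information(s3, c(0.01, 0.1))
  expect_equal(unname(F3), unname(F[pp, pp]), tolerance = 1e-12)
})

test_that("fim() wrapper assembles a coherent report", {
  rep <- fim(glycolysis_model(), n = 60, noise_level = 0.1, seed = 2,
             scale = "natural")
  expect_s3_class(rep, "sbinn_fim")
  K <- 14
  expect_equal(dim(rep$F), c(K, K))
  expect_equal(unname(diag(rep$R)), rep(1, K))
  expect_true(all(abs(rep$R[!is.na(rep$R)]) <= 1 + 1e-9))
  expect_true(all(rep$stds >= 0))
  # symmetric PSD to numerical tolerance
  expect_equal(rep$F, t(rep$F))
  expect_gt(min(rep$eigenvalues) / max(rep$eigenvalues), -1e-12)
  # cross-check the pseudo-inverse against an independent implementation on
  # a moderately conditioned PSD matrix (rank decisions are unambiguous)
  skip_if_not_installed("MASS")
  set.seed(4)
  A <- matrix(rnorm(14 * 14), 14)
  Fw <- crossprod(A) + diag(1e-4, 14)
  expect_equal(as.numeric(crb_stddev(Fw)),
               sqrt(pmax(diag(MASS::ginv(Fw)), 0)), tolerance = 1e-8)
})
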