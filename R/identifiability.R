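# Practical-identifiability toolkit. Output sensitivities come from the
# forward sensitivity equations d/dt (dx/dp) = (df/dx)(dx/dp) + df/dp,
# integrated jointly with the states; the Fisher Information Matrix under
# Gaussian observation noise is F = sum_{m,n} sigma_m^-2 s_mn s_mn', whose
# pseudo-inverse diagonal gives Cramer-Rao lower bounds on the parameter
# standard deviations.

#' Output sensitivities d y_m(t_n) / d p_k
#'
#' Integrates the forward sensitivity ODE system jointly with the states and
#' returns the sensitivity rows of the observed species at the observation
#' times. Initial-state sensitivities `dx0/dp` may be supplied for
#' parameters entering the initial condition (none of the benchmarks need
#' this).
#'
#' @param system an [ode_system()] with an analytic `jacobian` (all
#'   built-ins have one).
#' @param p parameter vector at which to linearize (defaults to nominal: the
#'   identifiability of a design is assessed at the generating values).
#' @param times observation times.
#' @param observables observed state indices; defaults to the system's.
#' @param dx0dp optional `S x K` matrix of initial-condition sensitivities.
#' @param rtol,atol solver tolerances.
#' @return matrix of dimension `(length(times) * M) x K`; rows are grouped
#'   by observable (all times of observable 1, then observable 2, ...), with
#'   the full `times x S x K` array in attribute `"array"`.
#' @export
output_sensitivities <- function(system, p = system$p_nominal, times,
                                 observables = system$observable_indices,
                                 dx0dp = NULL, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(system, "ode_system"))
  if (is.null(system$jacobian))
    stop("forward sensitivities require an analytic jacobian")
  S <- system$S; K <- system$K
  if (is.null(dx0dp)) dx0dp <- matrix(0, S, K)
  y0 <- c(as.numeric(system$x0), as.numeric(dx0dp))
  deriv <- function(t, y, parms) {
    x <- y[seq_len(S)]
    Sx <- matrix(y[-seq_len(S)], S, K)
    J <- system$jacobian(x, t, parms)
    dx <- system$rhs(x, t, parms)
    dSx <- J$Jx %*% Sx + J$Jp
    list(c(dx, as.numeric(dSx)))
  }
  tms <- sort(unique(c(system$time_domain[1], times)))
  out <- deSolve::ode(y = y0, times = tms, func = deriv, parms = p,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(tms)) stop("sensitivity integration failed")
  idx <- match(times, out[, 1])
  # drop the time column and the S state columns; the rest is vec(dx/dp)
  sens <- array(out[idx, -seq_len(S + 1), drop = FALSE],
                dim = c(length(times), S, K))
  rows <- do.call(rbind, lapply(observables, function(s)
    matrix(sens[, s, ], ncol = K)))
  dimnames(rows) <- list(NULL, system$param_names)
  attr(rows, "array") <- sens
  attr(rows, "observables") <- as.integer(observables)
  attr(rows, "n_times") <- length(times)
  rows
}

#' Fisher Information Matrix for a Gaussian observation design
#'
#' `F = sum_m sigma_m^-2 sum_n s_mn s_mn'`, where `s_mn` is the parameter
#' sensitivity of observable `m` at time `t_n` and `sigma_m` the noise
#' standard deviation of that observable. Independent observation blocks
#' add: the FIM of a combined design is the sum of the block FIMs.
#'
#' @param sensitivities matrix from [output_sensitivities()] (rows grouped
#'   by observable).
#' @param noise_stds per-observable noise standard deviations, all positive.
#' @return symmetric positive semidefinite `K x K` matrix.
#' @export
fisher_information <- function(sensitivities, noise_stds) {
  n_times <- attr(sensitivities, "n_times")
  M <- length(noise_stds)
  if (is.null(n_times)) {
    if (nrow(sensitivities) %% M != 0)
      stop("rows of sensitivities not a multiple of the number of observables")
    n_times <- nrow(sensitivities) / M
  }
  if (any(noise_stds <= 0))
    stop("noise standard deviations must be positive (zero-noise limit not defined)")
  K <- ncol(sensitivities)
  F <- matrix(0, K, K)
  for (m in seq_len(M)) {
    block <- sensitivities[(m - 1) * n_times + seq_len(n_times), , drop = FALSE]
    F <- F + crossprod(block) / noise_stds[m]^2
  }
  F <- (F + t(F)) / 2
  dimnames(F) <- list(colnames(sensitivities), colnames(sensitivities))
  F
}

# eigendecomposition-based pseudo-inverse with a relative rank cutoff
pinv_eigen <- function(F, rel_tol = 1e-10) {
  e <- eigen((F + t(F)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values))
  keep <- e$values > rel_tol * lmax
  Cinv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(pinv = Cinv, eigvals = e$values, eigvecs = e$vectors,
       rank = sum(keep), singular = any(!keep))
}

#' Cramer-Rao standard-deviation lower bounds
#'
#' `sigma_i = sqrt((F^+)_{ii})` using an eigendecomposition pseudo-inverse
#' with relative rank cutoff `rel_tol * lambda_max`. For a singular FIM the
#' bounds are computed on the identifiable subspace and the result carries
#' attribute `singular = TRUE`. These are lower bounds on any unbiased
#' estimator's standard deviation, not attained spreads.
#'
#' @param F Fisher information matrix.
#' @param rel_tol relative eigenvalue cutoff of the pseudo-inverse.
#' @return named vector of per-parameter bounds, with attribute `singular`.
#' @export
crb_stddev <- function(F, rel_tol = 1e-10) {
  pe <- pinv_eigen(F, rel_tol)
  s <- sqrt(pmax(diag(pe$pinv), 0))
  names(s) <- rownames(F)
  attr(s, "singular") <- pe$singular
  s
}

#' Parameter correlation matrix from the FIM
#'
#' `C = F^+`, `R_ij = C_ij / sqrt(C_ii C_jj)`. Nearly perfect correlations
#' (`|R_ij|` close to 1) flag parameter pairs that the design cannot
#' separate (practical non-identifiability). Entries whose variance is zero
#' under the pseudo-inverse are reported as `NA` rather than propagating
#' non-finite values.
#'
#' @inheritParams crb_stddev
#' @return `K x K` correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(F, rel_tol = 1e-10) {
  pe <- pinv_eigen(F, rel_tol)
  d <- diag(pe$pinv)
  R <- pe$pinv / sqrt(outer(d, d))
  R[!is.finite(R)] <- NA
  diag(R) <- 1
  dimnames(R) <- dimnames(F)
  R
}

#' Null eigenvectors of the FIM and their dominant parameters
#'
#' Eigenvectors with eigenvalues below `rel_tol * lambda_max` span the
#' directions in parameter space about which the observations carry (to
#' numerical precision) no information. For each null vector the parameter
#' with the largest-magnitude component is reported; such parameters are
#' practically non-identifiable under the design. Eigenvectors are
#' normalized to unit norm.
#'
#' @inheritParams crb_stddev
#' @return list with `vectors` (K x n_null matrix), `eigenvalues`,
#'   `dominant` (parameter index per null vector) and `dominant_names`.
#' @export
null_eigenvectors <- function(F, rel_tol = 1e-10) {
  e <- eigen((F + t(F)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values))
  null <- which(e$values < rel_tol * lmax)
  vecs <- e$vectors[, null, drop = FALSE]
  dom <- if (length(null)) apply(abs(vecs), 2, which.max) else integer(0)
  list(vectors = vecs, eigenvalues = e$values[null],
       all_eigenvalues = e$values,
       dominant = dom,
       dominant_names = rownames(F)[dom])
}

#' Full practical-identifiability report for an observation design
#'
#' Convenience wrapper reproducing the whole analysis for a benchmark
#' design: samples the observation times, computes the clean observables and
#' the proportional noise scales `sigma_m = c * sd_m`, integrates the
#' forward sensitivities, and assembles the FIM, the Cramer-Rao bounds, the
#' correlation matrix and the null-eigenvector report.
#'
#' @param system an [ode_system()].
#' @param n number of observation times.
#' @param window observation window (defaults to the time domain).
#' @param observables observed state indices.
#' @param noise_level proportional noise constant `c > 0`.
#' @param seed seed for the sampled design; set `times` to override.
#' @param times explicit observation times (otherwise sampled).
#' @param p evaluation point (defaults to nominal values).
#' @param rel_tol pseudo-inverse / null-space relative cutoff.
#' @param scale `"log"` (default) analyses the information about *relative*
#'   parameter perturbations (sensitivities with respect to `log p`), the
#'   meaningful convention for kinetic parameters spanning many decades;
#'   `"natural"` uses raw parameter units. Reported standard-deviation
#'   bounds are always on the natural scale (for `"log"` they are
#'   `p_i * sigma_{log,i}`).
#' @return an object of class `sbinn_fim`: list with `F`, `stds`, `R`,
#'   `eigenvalues`, `null` (from [null_eigenvectors()]), `noise_stds` and
#'   the design.
#' @export
fim <- function(system, n = 100, window = system$time_domain,
                observables = system$observable_indices, noise_level = 0.1,
                seed = 1, times = NULL, p = system$p_nominal,
                rel_tol = 1e-10, scale = c("log", "natural")) {
  scale <- match.arg(scale)
  if (is.null(times)) times <- sample_observation_times(n, window, seed = seed)
  grid <- sort(unique(c(window[1], times)))
  traj <- solve_reference(system, p, grid)
  clean <- traj[match(times, grid), observables + 1, drop = FALSE]
  noise_stds <- noise_level * apply(clean, 2, stats::sd)
  sens <- output_sensitivities(system, p, times, observables)
  if (scale == "log") {
    nt <- attr(sens, "n_times")
    sens <- sweep(sens, 2, as.numeric(p), "*")
    attr(sens, "n_times") <- nt
  }
  F <- fisher_information(sens, noise_stds)
  stds <- crb_stddev(F, rel_tol)
  if (scale == "log") {
    sing <- attr(stds, "singular")
    stds <- stds * as.numeric(p)
    attr(stds, "singular") <- sing
  }
  structure(list(
    F = F, scale = scale,
    stds = stds,
    R = correlation_matrix(F, rel_tol),
    eigenvalues = eigen((F + t(F)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values,
    null = null_eigenvectors(F, rel_tol),
    noise_stds = noise_stds,
    design = list(model = system$name, n = length(times), window = window,
                  observables = observables, noise_level = noise_level,
                  seed = seed, rel_tol = rel_tol)
  ), class = "sbinn_fim")
}

#' @export
print.sbinn_fim <- function(x, ...) {
  cat(sprintf("Fisher-information identifiability report (%s design)\n",
              x$design$model))
  cat(sprintf("  %d observations of %d observable(s), noise c = %g\n",
              x$design$n, length(x$design$observables),
              x$design$noise_level))
  cat("  Cramer-Rao standard-deviation lower bounds:\n")
  print(signif(x$stds, 3))
  nn <- length(x$null$dominant)
  if (nn) {
    cat(sprintf("  %d null eigenvectors; dominant parameters: %s\n", nn,
                paste(x$null$dominant_names, collapse = ", ")))
  } else cat("  FIM is numerically full rank (no null eigenvectors)\n")
  invisible(x)
}
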