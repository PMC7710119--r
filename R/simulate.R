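# Synthetic-experiment generation: reference trajectories, randomly timed
# observations of selected species, proportional Gaussian noise, two-instant
# auxiliary records, and the delimited-text dataset format.

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Solve an ODE system at reference accuracy
#'
#' Integrates the system with a variable-step, stiff-capable solver
#' (deSolve's `lsoda` by default) at tight tolerances. Used both for
#' generating synthetic data and as the ground truth that inferred dynamics
#' and forecasts are compared against. Evaluation times beyond the system's
#' time domain are allowed (forecasting).
#'
#' @param system an [ode_system()].
#' @param p parameter vector; defaults to the nominal values.
#' @param times sorted evaluation time grid.
#' @param x0 initial state; defaults to the system's.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integrator name.
#' @return numeric matrix with columns `time` and one per state.
#' @export
solve_reference <- function(system, p = system$p_nominal, times,
                            x0 = system$x0, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda") {
  stopifnot(inherits(system, "ode_system"), !is.unsorted(times))
  tms <- unique(c(times[1], times))
  if (tms[1] > system$time_domain[1]) tms <- c(system$time_domain[1], tms)
  deriv <- function(t, y, parms) list(system$rhs(y, t, parms))
  out <- deSolve::ode(y = as.numeric(x0), times = tms, func = deriv,
                      parms = p, method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(tms)) {
    tfail <- if (nrow(out) >= 1) out[nrow(out), 1] else tms[1]
    stop(sprintf("integration of '%s' failed near t = %g", system$name, tfail))
  }
  out <- out[match(times, out[, 1]), , drop = FALSE]
  colnames(out) <- c("time", system$state_names)
  unclass(out)
}

#' Draw random observation times
#'
#' Observation instants are i.i.d. uniform on the window, mirroring
#' scattered experimental sampling. Reproducible under `seed`.
#'
#' @param n number of observations.
#' @param window length-2 numeric `c(a, b)`, `a < b`.
#' @param seed optional integer seed (the global RNG state is restored).
#' @return sorted numeric vector of length `n`.
#' @export
sample_observation_times <- function(n, window, seed = NULL) {
  stopifnot(n >= 1, length(window) == 2, window[1] < window[2])
  sort(with_seed(seed, stats::runif(n, window[1], window[2])))
}

#' Corrupt clean observations with proportional Gaussian noise
#'
#' Adds zero-mean Gaussian noise to each observable column with standard
#' deviation `c * sd_m`, where `sd_m` is the empirical standard deviation of
#' that observable's clean values over the observation window (what an
#' experimenter would estimate from the sampled data).
#'
#' @param clean numeric matrix, one column per observable.
#' @param noise_level the proportionality constant `c >= 0`; `0` returns the
#'   input unchanged.
#' @param seed optional integer seed.
#' @return matrix of the same shape as `clean`.
#' @export
corrupt <- function(clean, noise_level, seed = NULL) {
  if (noise_level < 0) stop("noise level c must be non-negative")
  clean <- as.matrix(clean)
  if (noise_level == 0) return(clean)
  with_seed(seed, {
    noisy <- clean
    for (m in seq_len(ncol(clean))) {
      s <- stats::sd(clean[, m])
      noisy[, m] <- clean[, m] + stats::rnorm(nrow(clean), 0, noise_level * s)
    }
    noisy
  })
}

#' Generate a synthetic observation dataset
#'
#' Produces the full synthetic experiment used for training: a reference
#' trajectory at nominal parameters, `n` observations of the selected
#' species at random times corrupted with proportional Gaussian noise, and
#' the two-instant auxiliary record (the noiseless full state at `T0`, the
#' window start, and at `T1`). Auxiliary records are stored noiseless by
#' default (the initial condition is treated as given); set
#' `corrupt_aux = TRUE` for robustness studies.
#'
#' @param system an [ode_system()].
#' @param p generating parameter vector (defaults to nominal).
#' @param n number of observations.
#' @param window observation time window; defaults to the system time domain.
#' @param observables 1-based state indices observed; defaults to the
#'   system's.
#' @param noise_level proportional noise constant `c`.
#' @param t1 auxiliary time instant `T1`; defaults to the window end.
#' @param seed integer seed controlling sampling times and noise.
#' @param corrupt_aux also corrupt the auxiliary full-state records.
#' @return an object of class `sbinn_data`: list with `observations`
#'   (times, values, clean, observable_indices, noise_level, seed), `aux`
#'   (T0, x_T0, T1, x_T1) and `design`.
#' @export
make_dataset <- function(system, p = system$p_nominal, n = 100,
                         window = system$time_domain,
                         observables = system$observable_indices,
                         noise_level = 0, t1 = window[2], seed = 1,
                         corrupt_aux = FALSE) {
  stopifnot(inherits(system, "ode_system"))
  if (t1 <= window[1] || t1 > window[2])
    stop("T1 must lie in the observation window and differ from T0")
  times <- sample_observation_times(n, window, seed = seed)
  grid <- sort(unique(c(window[1], times, t1)))
  traj <- solve_reference(system, p, grid)
  idx <- match(times, grid)
  clean <- traj[idx, observables + 1, drop = FALSE]
  values <- corrupt(clean, noise_level,
                    seed = if (is.null(seed)) NULL else seed + 1L)
  x_t0 <- traj[match(window[1], grid), -1]
  x_t1 <- traj[match(t1, grid), -1]
  if (corrupt_aux && noise_level > 0) {
    sds <- apply(traj[idx, -1, drop = FALSE], 2, stats::sd)
    noise <- with_seed(if (is.null(seed)) NULL else seed + 2L,
                       stats::rnorm(2 * system$S, 0, noise_level * rep(sds, 2)))
    x_t0 <- x_t0 + noise[seq_len(system$S)]
    x_t1 <- x_t1 + noise[system$S + seq_len(system$S)]
  }
  structure(list(
    observations = list(
      times = times,
      values = `colnames<-`(values, system$state_names[observables]),
      clean = `colnames<-`(clean, system$state_names[observables]),
      observable_indices = as.integer(observables),
      noise_level = noise_level, seed = seed),
    aux = list(T0 = window[1], x_T0 = x_t0, T1 = t1, x_T1 = x_t1),
    design = list(model = system$name, n = n, window = window,
                  observables = as.integer(observables),
                  noise_level = noise_level, t1 = t1, seed = seed)
  ), class = "sbinn_data")
}

#' @export
print.sbinn_data <- function(x, ...) {
  o <- x$observations
  cat(sprintf("sbinn_data: %d observations of (%s) on [%g, %g], noise c = %g\n",
              length(o$times), paste(colnames(o$values), collapse = ", "),
              min(o$times), max(o$times), o$noise_level))
  cat(sprintf("  auxiliary full states at T0 = %g and T1 = %g\n",
              x$aux$T0, x$aux$T1))
  invisible(x)
}

#' Write / read a dataset as delimited text plus JSON sidecar
#'
#' Observations go to `<prefix>_observations.csv` (columns: `t` then one per
#' observed species); the auxiliary records and design metadata (including
#' seeds) go to `<prefix>_meta.json`. The round trip is exact for the times
#' and values written.
#'
#' @param data an `sbinn_data` object.
#' @param prefix file path prefix.
#' @return `write_dataset` returns the two file paths invisibly;
#'   `read_dataset` returns an `sbinn_data` object.
#' @export
write_dataset <- function(data, prefix) {
  stopifnot(inherits(data, "sbinn_data"))
  csv <- paste0(prefix, "_observations.csv")
  js <- paste0(prefix, "_meta.json")
  df <- data.frame(t = data$observations$times, data$observations$values,
                   check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(aux = data$aux, design = data$design,
               observable_indices = data$observations$observable_indices,
               noise_level = data$observations$noise_level,
               seed = data$observations$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), js)
  invisible(c(csv, js))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  csv <- paste0(prefix, "_observations.csv")
  js <- paste0(prefix, "_meta.json")
  df <- utils::read.csv(csv, check.names = FALSE)
  meta <- jsonlite::fromJSON(readLines(js))
  vals <- as.matrix(df[, -1, drop = FALSE])
  structure(list(
    observations = list(
      times = df$t, values = vals, clean = NULL,
      observable_indices = as.integer(meta$observable_indices),
      noise_level = meta$noise_level, seed = meta$seed),
    aux = list(T0 = meta$aux$T0, x_T0 = unlist(meta$aux$x_T0),
               T1 = meta$aux$T1, x_T1 = unlist(meta$aux$x_T1)),
    design = meta$design
  ), class = "sbinn_data")
}
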