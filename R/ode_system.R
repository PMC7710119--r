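#' Define an ODE system for surrogate-based inference
#'
#' An `ode_system` bundles everything the surrogate trainer, the reference
#' solver and the identifiability toolkit need to know about a kinetic model:
#' state and parameter labels, nominal (generating) parameter values, the
#' initial state, the time domain, which species are experimentally
#' observable, the right-hand side \eqn{f(x, t; p)} and, optionally, its
#' analytic Jacobians.
#'
#' @param name identifier for the system.
#' @param state_names character vector of state labels (length `S`).
#' @param param_names character vector of parameter labels (length `K`).
#' @param p_nominal numeric vector of nominal/target parameter values.
#' @param x0 initial state at the start of the time domain.
#' @param time_domain numeric length-2 vector `c(T0, T_end)` in the model's
#'   native time unit (minutes or hours; no internal conversion is done).
#' @param observable_indices strictly increasing 1-based indices of the
#'   measured species.
#' @param rhs function `(x, t, p) -> dx/dt` returning a length-`S` numeric
#'   vector.
#' @param output_magnitudes order-of-magnitude of each state's mean value,
#'   used as the surrogate's output scales.
#' @param derivative_magnitudes order-of-magnitude of each state's time
#'   derivative over the time domain (same units as `rhs`), used to
#'   normalize the per-state residual weights; defaults to
#'   `output_magnitudes / (time span / 10)`.
#' @param jacobian optional function `(x, t, p) -> list(Jx, Jp)` with the
#'   `S x S` state Jacobian and `S x K` parameter Jacobian. Required for
#'   forward-sensitivity analysis of user models; supplied automatically for
#'   the built-in benchmarks.
#' @param schedule optional [nutrition_schedule()] of exogenous meal forcing
#'   (ultradian model).
#' @param model_id internal id of the compiled right-hand side (0 for user
#'   models).
#' @return an object of class `ode_system`.
#' @seealso [glycolysis_model()], [apoptosis_model()], [ultradian_model()]
#' @export
ode_system <- function(name, state_names, param_names, p_nominal, x0,
                       time_domain, observable_indices, rhs,
                       output_magnitudes, jacobian = NULL, schedule = NULL,
                       model_id = 0L, derivative_magnitudes = NULL) {
  S <- length(state_names)
  K <- length(param_names)
  stopifnot(S >= 1, length(x0) == S, length(p_nominal) == K,
            length(output_magnitudes) == S, length(time_domain) == 2,
            time_domain[1] < time_domain[2])
  obs <- as.integer(observable_indices)
  if (length(obs) < 1 || length(obs) > S || any(obs < 1) || any(obs > S) ||
      is.unsorted(obs, strictly = TRUE))
    stop("observable_indices must be strictly increasing indices in 1..S")
  f0 <- rhs(x0, time_domain[1], p_nominal)
  if (length(f0) != S || !all(is.finite(f0)))
    stop("rhs evaluated at (x0, T0, p_nominal) must be finite of length S")
  structure(list(
    name = name, S = S, K = K,
    state_names = state_names, param_names = param_names,
    p_nominal = stats::setNames(as.numeric(p_nominal), param_names),
    x0 = stats::setNames(as.numeric(x0), state_names),
    time_domain = as.numeric(time_domain),
    observable_indices = obs,
    rhs = rhs, jacobian = jacobian,
    output_magnitudes = as.numeric(output_magnitudes),
    derivative_magnitudes = if (is.null(derivative_magnitudes))
      as.numeric(output_magnitudes) / (diff(as.numeric(time_domain)) / 10)
      else as.numeric(derivative_magnitudes),
    schedule = schedule, model_id = as.integer(model_id)
  ), class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("ODE system:", x$name, "\n")
  cat(sprintf("  %d states: %s\n", x$S, paste(x$state_names, collapse = ", ")))
  cat(sprintf("  %d parameters, time domain [%g, %g]\n", x$K,
              x$time_domain[1], x$time_domain[2]))
  cat("  observables:", paste(x$state_names[x$observable_indices],
                              collapse = ", "), "\n")
  if (!is.null(x$schedule))
    cat(sprintf("  %d nutrition events\n", length(x$schedule$times)))
  invisible(x)
}

# schedule vectors for the compiled RHS (empty for non-forced models)
schedule_vectors <- function(system) {
  if (is.null(system$schedule)) list(t = numeric(0), m = numeric(0))
  else list(t = system$schedule$times, m = system$schedule$masses)
}

#' Registry of built-in benchmark systems
#'
#' Looks up one of the shipped benchmarks by name: `"glycolysis"`,
#' `"apoptosis"` or `"ultradian"`. Extra arguments are passed to the model
#' constructor (e.g. `x7_0` for the apoptosis survival/death scenarios).
#'
#' @param name model name.
#' @param ... passed to the model constructor.
#' @return an [ode_system()].
#' @export
get_model <- function(name, ...) {
  switch(match.arg(name, c("glycolysis", "apoptosis", "ultradian")),
         glycolysis = glycolysis_model(...),
         apoptosis = apoptosis_model(...),
         ultradian = ultradian_model(...))
}

# --- nutrition forcing -------------------------------------------------------

#' Meal schedule for the ultradian glucose-insulin model
#'
#' The exogenous glucose appearance rate is a sum of exponentially decaying
#' pulses, one per nutrition event: \deqn{I_G(t) = \sum_j m_j k
#' \exp(k (t_j - t)) \quad (t \ge t_j),} where `t_j` is the meal time (min),
#' `m_j` the carbohydrate content (g) and `k` the decay constant (1/min).
#' Integrated over all time after the event, each pulse delivers exactly
#' `m_j` grams.
#'
#' @param times event times in minutes, sorted increasing.
#' @param masses carbohydrate contents in grams, all positive.
#' @param decay decay constant `k` in 1/min.
#' @return an object of class `nutrition_schedule`.
#' @export
nutrition_schedule <- function(times = c(300, 650, 1100),
                               masses = c(60, 40, 50),
                               decay = 0.0083) {
  stopifnot(length(times) == length(masses), decay > 0)
  if (length(times)) {
    stopifnot(all(times >= 0), all(masses > 0))
    if (is.unsorted(times)) stop("event times must be sorted increasing")
  }
  structure(list(times = as.numeric(times), masses = as.numeric(masses),
                 decay = as.numeric(decay)),
            class = "nutrition_schedule")
}

#' Exogenous glucose appearance rate
#'
#' Evaluates the nutritional driver \eqn{I_G(t)} of a meal schedule, summing
#' only events that have already occurred (`t_j <= t`). The rate is returned
#' in the schedule's mass unit per minute (g/min for the benchmark schedule).
#'
#' @param t time(s) in minutes; vectorized.
#' @param schedule a [nutrition_schedule()].
#' @return numeric vector of appearance rates, `>= 0`.
#' @export
nutrition_driver <- function(t, schedule) {
  stopifnot(inherits(schedule, "nutrition_schedule"), all(is.finite(t)))
  k <- schedule$decay
  vapply(t, function(ti) {
    on <- schedule$times <= ti
    sum(schedule$masses[on] * k * exp(k * (schedule$times[on] - ti)))
  }, numeric(1))
}
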