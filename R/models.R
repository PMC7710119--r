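# Built-in benchmark systems. Each constructor returns an ode_system whose
# rhs/jacobian dispatch to the compiled implementations, so the reference
# solver, the training loss and the sensitivity equations share one source.

#' Yeast glycolytic oscillator (7 species, 14 parameters)
#'
#' The standard seven-species model of sustained glycolytic oscillations in
#' yeast extracts. Glucose is supplied at constant influx `J0`; the committed
#' step (flux `v = k1 S1 S6 / (1 + (S6/K1)^q)`) is allosterically inhibited
#' by ATP (`S6`) through a Hill term with exponent `q`, which generates the
#' limit cycle. `S5` is NADH and `S6` is ATP; these two species are the
#' default observables. Concentrations are in mM, time in minutes.
#'
#' Parameter order: `J0, k1, k2, k3, k4, k5, k6, k, kappa, q, K1, psi, N, A`,
#' where `N` is the total NAD pool and `A` the total adenine-nucleotide pool.
#' The initial state is a point on the limit cycle so the training window
#' starts inside the oscillatory regime.
#'
#' @return an [ode_system()].
#' @export
glycolysis_model <- function() {
  p <- c(J0 = 2.5, k1 = 100, k2 = 6, k3 = 16, k4 = 100, k5 = 1.28, k6 = 12,
         k = 1.8, kappa = 13, q = 4, K1 = 0.52, psi = 0.1, N = 1, A = 4)
  x0 <- c(S1 = 1.5726, S2 = 0.6016, S3 = 0.0711, S4 = 0.1185, S5 = 0.1480,
          S6 = 1.4859, S7 = 0.0529)
  ode_system(
    name = "glycolysis",
    state_names = names(x0), param_names = names(p),
    p_nominal = p, x0 = x0,
    time_domain = c(0, 10),
    observable_indices = c(5L, 6L),
    rhs = function(x, t, p) {
      if (!all(is.finite(x))) stop("non-finite state passed to glycolysis rhs")
      if (length(p) != 14) stop("glycolysis parameter vector must have length 14")
      if (p[[11]] == 0) stop("K1 must be non-zero (Hill term)")
      drop(cpp_model_f(1L, matrix(x, nrow = 1), t, p, numeric(0), numeric(0)))
    },
    jacobian = function(x, t, p) cpp_model_jac(1L, x, t, p, numeric(0),
                                               numeric(0))[c("Jx", "Jp")],
    output_magnitudes = c(1, 1, 0.1, 0.2, 0.1, 2, 0.1),
    derivative_magnitudes = c(4, 6, 0.3, 0.6, 0.25, 7, 0.1),
    model_id = 1L)
}

#' Caspase-cascade cell apoptosis model (8 species, 9 rate constants)
#'
#' A mass-action sub-network of the receptor-induced programmed-cell-death
#' decision: active effector caspase (`x4`) activates initiator caspase
#' (`x1 -> x2`, via the complex `x5`), active initiator caspase activates
#' effector caspase (`x3 -> x4`, via `x6`), and an inhibitor-of-apoptosis
#' protein (`x7`) sequesters `x4` into a complex (`x8`) that degrades it.
#' The positive caspase feedback against stoichiometric inhibition makes the
#' outcome bistable: with abundant inhibitor (`x7(0) = 2.9e4` molecules/cell)
#' the death signal is quenched (cell survival), with a ten-fold lower level
#' (`x7(0) = 2.9e3`) effector caspase escapes inhibition (cell death).
#'
#' States are copy numbers (molecules/cell), time is in hours. Rate constants
#' are quoted per second (bimolecular constants per molecule per second) and
#' the right-hand side carries the 3600 s/h conversion, so derivatives are in
#' molecules/cell/hour. Parameter order:
#' `k1, kd1, kd2, k3, kd3, kd4, k5, kd5, kd6`. The only default observable is
#' `x4`.
#'
#' @param x7_0 initial inhibitor copy number; `2.9e4` selects the survival
#'   scenario, `2.9e3` the death scenario.
#' @return an [ode_system()].
#' @export
apoptosis_model <- function(x7_0 = 2.9e4) {
  p <- c(k1 = 2.67e-9, kd1 = 1e-2, kd2 = 8e-3, k3 = 6.8e-8, kd3 = 5e-2,
         kd4 = 1e-3, k5 = 7e-5, kd5 = 1.67e-5, kd6 = 1.67e-4)
  x0 <- c(x1 = 1.34e5, x2 = 1e4, x3 = 2.67e5, x4 = 0, x5 = 0, x6 = 0,
          x7 = x7_0, x8 = 0)
  # state and derivative magnitudes differ strongly between the phenotypes
  if (x7_0 >= 1e4) {  # survival
    mags <- c(1e5, 1e4, 1e5, 1, 1e-2, 1e3, 1e4, 1e4)
    dmags <- c(1, 1e4, 1e4, 0.1, 0.01, 1e4, 1e3, 1e3)
  } else {            # death
    mags <- c(1e4, 1e5, 1e4, 1e5, 1e2, 1e3, 1e2, 1e3)
    dmags <- c(5e3, 2e4, 2e4, 1e4, 1e2, 2e4, 6e2, 6e2)
  }
  ode_system(
    name = "apoptosis",
    state_names = names(x0), param_names = names(p),
    p_nominal = p, x0 = x0,
    time_domain = c(0, 60),
    observable_indices = 4L,
    rhs = function(x, t, p) {
      if (length(p) != 9) stop("apoptosis parameter vector must have length 9")
      if (any(x < 0) && min(x) < -1e-6 * max(abs(x)))
        warning("negative state values passed to apoptosis rhs")
      drop(cpp_model_f(2L, matrix(x, nrow = 1), t, p, numeric(0), numeric(0)))
    },
    jacobian = function(x, t, p) cpp_model_jac(2L, x, t, p, numeric(0),
                                               numeric(0))[c("Jx", "Jp")],
    output_magnitudes = mags,
    derivative_magnitudes = dmags,
    model_id = 2L)
}

#' Ultradian glucose-insulin model with meal forcing (6 states, 20 parameters)
#'
#' The six-state ultradian endocrine model: plasma insulin `Ip` (mU),
#' interstitial insulin `Ii` (mU), total glucose `G` (mg) and a three-stage
#' linear filter `h1, h2, h3` (mU) that delays the effect of plasma insulin
#' on hepatic glucose production. Time is in minutes. Insulin secretion,
#' insulin-independent and insulin-dependent glucose utilization and hepatic
#' production are the usual sigmoidal/exponential response functions
#' `f1(G), f2(G), f3(Ii) G, f4(h3)`. Exogenous glucose appears through the
#' meal driver \eqn{I_G(t)} of a [nutrition_schedule()]; meal masses are in
#' grams and the glucose compartment in mg, so the driver enters the ODE
#' scaled by 1000 mg/g.
#'
#' Parameter order: `Vp, Vi, Vg, E, tp, ti, td, k, Rm, a1, C1, C2, C4, C5,
#' Ub, U0_C3, Um_C3, Rg, alpha, beta`. The insulin-dependent uptake is
#' parameterized directly in the combined quantities `U0/C3` and `Um/C3` to
#' avoid a non-identifiable split. The decay constant `k` of the meal driver
#' is a model parameter (so it can be inferred); the schedule's own `decay`
#' field is only the nominal value used when simulating.
#'
#' @param schedule a [nutrition_schedule()]; the default is the benchmark
#'   three-meal day. An empty schedule (`nutrition_schedule(numeric(0),
#'   numeric(0))`) gives the autonomous system.
#' @return an [ode_system()].
#' @export
ultradian_model <- function(schedule = nutrition_schedule()) {
  stopifnot(inherits(schedule, "nutrition_schedule"))
  p <- c(Vp = 3, Vi = 11, Vg = 10, E = 0.2, tp = 6, ti = 100, td = 12,
         k = 0.0083, Rm = 209, a1 = 6.6, C1 = 300, C2 = 144, C4 = 80,
         C5 = 26, Ub = 72, U0_C3 = 0.04, Um_C3 = 0.9, Rg = 180,
         alpha = 7.5, beta = 1.772)
  # basal state: the fixed point of the autonomous (meal-free) system
  x0 <- c(Ip = 50.090565, Ii = 118.493811, G = 10677.452537,
          h1 = 50.090565, h2 = 50.090565, h3 = 50.090565)
  sched <- schedule
  ode_system(
    name = "ultradian",
    state_names = names(x0), param_names = names(p),
    p_nominal = p, x0 = x0,
    time_domain = c(0, 1800),
    observable_indices = 3L,
    rhs = function(x, t, p) {
      if (!is.finite(p[[7]]) || p[[7]] <= 0) stop("td must be positive")
      drop(cpp_model_f(3L, matrix(x, nrow = 1), t, p, sched$times,
                       sched$masses))
    },
    jacobian = function(x, t, p) cpp_model_jac(3L, x, t, p, sched$times,
                                               sched$masses)[c("Jx", "Jp")],
    output_magnitudes = c(100, 100, 1e4, 100, 100, 100),
    derivative_magnitudes = c(3, 3, 100, 2, 2, 1.5),
    schedule = sched,
    model_id = 3L)
}
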