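# Composite loss: supervised data term on the observed species, the
# ODE-residual (collocation) term tying the surrogate's analytic time
# derivative to the model right-hand side, and the two-instant auxiliary
# term on the full state. The heavy lifting lives in the compiled kernel;
# these wrappers expose the individual terms with the package's containers.

empty_events <- function() {
  list(ev_t = numeric(0), ev_m = numeric(0), m_free = FALSE, t_free = FALSE,
       evm_raw_idx = integer(0), evt_raw_idx = integer(0),
       t_lo = numeric(0), t_hi = numeric(0), order_penalty = 0)
}

# assemble the static arguments of cpp_loss_grad for one training problem
make_problem <- function(system, data, config, space, tau,
                         w_data = NULL, w_ode = NULL, w_aux = NULL,
                         events = empty_events()) {
  S <- system$S
  obs <- data$observations
  M <- length(obs$observable_indices)
  list(
    dims = config_dims(config, S),
    feats = config$feat_codes,
    omega = config$feature_scale,
    t_scale = config$t_scale,
    kout = config$output_scales,
    model_id = system$model_id,
    ptype = space$type, pfix = space$pfix, plo = space$lo, phi = space$hi,
    pref = if (is.null(space$pref)) rep(1, length(space$type))
           else space$pref,
    praw_idx = space$praw_idx,
    events = events,
    t_data = obs$times, y_data = unname(obs$values),
    obs_idx = obs$observable_indices,
    tau = tau,
    t_aux = c(data$aux$T0, data$aux$T1),
    x_aux = rbind(unname(data$aux$x_T0), unname(data$aux$x_T1)),
    w_data = if (is.null(w_data)) rep(1, M) else rep_len(w_data, M),
    w_ode = if (is.null(w_ode)) rep(1, S) else rep_len(w_ode, S),
    w_aux = if (is.null(w_aux)) rep(1, S) else rep_len(w_aux, S),
    user_model = if (system$model_id == 0L) user_model_callback(system),
    system = system, space = space, config = config
  )
}

#' Inverse-scale loss weights
#'
#' Deterministic weight choice keeping the weighted loss terms at the same
#' order of magnitude: each data term is divided by the empirical variance of
#' its observable, each auxiliary term by the squared state magnitude
#' `k_s^2`, and each residual term by the squared characteristic derivative
#' magnitude `d_s^2` of its state (the system's `derivative_magnitudes`).
#'
#' @param system an [ode_system()].
#' @param data an `sbinn_data` object.
#' @param config an [sbinn_config()].
#' @return list with `w_data`, `w_ode`, `w_aux`.
#' @export
normalized_weights <- function(system, data, config) {
  k <- config$output_scales
  list(w_data = 1 / pmax(apply(data$observations$values, 2, stats::var),
                         1e-12),
       w_ode = 1 / system$derivative_magnitudes^2,
       w_aux = 1 / k^2)
}

# vectorized rhs/jacobian callback for training user-defined systems
user_model_callback <- function(system) {
  if (is.null(system$jacobian))
    stop("training a user-defined system requires an analytic jacobian")
  S <- system$S; K <- system$K
  function(X, tau, p, want_grad) {
    n <- length(tau)
    F <- matrix(0, n, S)
    Jx <- array(0, c(S, S, n))
    Jp <- array(0, c(S, K, n))
    for (i in seq_len(n)) {
      F[i, ] <- system$rhs(X[i, ], tau[i], p)
      if (want_grad) {
        J <- system$jacobian(X[i, ], tau[i], p)
        Jx[, , i] <- J$Jx
        Jp[, , i] <- J$Jp
      }
    }
    list(F = F, Jx = Jx, Jp = Jp)
  }
}

eval_loss <- function(theta, raw, prob, stage, want_grad = TRUE) {
  ev <- prob$events
  cpp_loss_grad(theta, prob$dims, prob$feats, prob$omega, prob$t_scale,
                prob$kout,
                prob$model_id, raw, prob$ptype, prob$pfix, prob$plo,
                prob$phi, prob$pref, prob$praw_idx,
                ev$ev_t, ev$ev_m, ev$m_free, ev$t_free,
                ev$evm_raw_idx, ev$evt_raw_idx, ev$t_lo, ev$t_hi,
                ev$order_penalty,
                prob$t_data, prob$y_data, prob$obs_idx, prob$tau,
                prob$t_aux, prob$x_aux,
                prob$w_data, prob$w_ode, prob$w_aux,
                as.integer(stage), want_grad, prob$user_model)
}

loss_breakdown <- function(res, prob) {
  structure(list(
    data_terms = stats::setNames(as.numeric(res$data_terms),
      prob$system$state_names[prob$obs_idx]),
    ode_terms = stats::setNames(as.numeric(res$ode_terms),
      prob$system$state_names),
    aux_terms = stats::setNames(as.numeric(res$aux_terms),
      prob$system$state_names),
    weights = list(data = prob$w_data, ode = prob$w_ode, aux = prob$w_aux),
    penalty = res$penalty,
    total = res$total
  ), class = "sbinn_loss")
}

#' @export
print.sbinn_loss <- function(x, ...) {
  cat("total loss:", format(x$total, digits = 6), "\n")
  cat("  data terms:", paste(format(x$data_terms, digits = 4),
                             collapse = " "), "\n")
  cat("  ode terms: ", paste(format(x$ode_terms, digits = 4),
                             collapse = " "), "\n")
  cat("  aux terms: ", paste(format(x$aux_terms, digits = 4),
                             collapse = " "), "\n")
  invisible(x)
}

# a parameter space with everything fixed at p (no trainables)
fixed_space <- function(system, p) {
  structure(list(param_names = system$param_names,
                 type = rep(0L, system$K), pfix = as.numeric(p),
                 lo = 0.5 * as.numeric(p), hi = 1.5 * as.numeric(p) + 1e-12,
                 praw_idx = rep(-1L, system$K), n_raw = 0L,
                 raw_init = numeric(0)),
            class = "parameter_space")
}

#' Individual loss terms of the composite objective
#'
#' `data_loss` is the mean squared mismatch between the surrogate and the
#' noisy observations, per observable:
#' `sum_m w_m * mean_n (y_m(t_n) - x_hat_{s_m}(t_n))^2`.
#' `ode_residual_loss` penalizes the surrogate's analytic time derivative
#' against the model right-hand side on the collocation grid:
#' `sum_s w_s * mean_n (dx_hat_s/dt(tau_n) - f_s(x_hat(tau_n), tau_n; p))^2`.
#' `aux_loss` ties the surrogate to the full state at the two auxiliary
#' instants: `sum_s w_s * ((x_s(T0)-x_hat_s(T0))^2 +
#' (x_s(T1)-x_hat_s(T1))^2) / 2`.
#'
#' @param data an `sbinn_data` object (only the relevant part is used).
#' @param theta flattened network weights.
#' @param config an [sbinn_config()].
#' @param system an [ode_system()].
#' @param weights per-term weights (recycled).
#' @param p natural-scale parameter vector for the residual term.
#' @param tau collocation time points.
#' @return list with `value` (weighted sum) and `terms` (unweighted
#'   per-term values).
#' @export
data_loss <- function(data, theta, config, system, weights = 1) {
  obs <- data$observations
  if (any(obs$observable_indices < 1) || any(obs$observable_indices > system$S))
    stop("observable index outside 1..S")
  if (!length(obs$times)) stop("empty observation set")
  xh <- surrogate_forward(theta, config, obs$times)
  terms <- vapply(seq_along(obs$observable_indices), function(m)
    mean((obs$values[, m] - xh[, obs$observable_indices[m]])^2), numeric(1))
  w <- rep_len(weights, length(terms))
  list(value = sum(w * terms),
       terms = stats::setNames(terms,
                               system$state_names[obs$observable_indices]))
}

#' @rdname data_loss
#' @export
ode_residual_loss <- function(theta, p, system, tau, config, weights = 1) {
  td <- system$time_domain
  if (any(tau < td[1] - 1e-9) || any(tau > td[2] + 1e-9))
    stop("collocation points must lie within the time domain")
  xh <- surrogate_forward(theta, config, tau, deriv = TRUE)
  sv <- schedule_vectors(system)
  f <- if (system$model_id == 0L) {
    t(vapply(seq_along(tau),
             function(i) as.numeric(system$rhs(xh[i, ], tau[i], p)),
             numeric(system$S)))
  } else {
    cpp_model_f(system$model_id, xh, tau, as.numeric(p), sv$t, sv$m)
  }
  if (!all(is.finite(f))) {
    bad <- which(!is.finite(rowSums(f)))[1]
    stop(sprintf("rhs evaluation failed at collocation point t = %g", tau[bad]))
  }
  res <- attr(xh, "dxdt") - f
  terms <- colMeans(res^2)
  w <- rep_len(weights, system$S)
  list(value = sum(w * terms),
       terms = stats::setNames(terms, system$state_names))
}

#' @rdname data_loss
#' @export
aux_loss <- function(data, theta, config, system, weights = 1) {
  aux <- data$aux
  xh <- surrogate_forward(theta, config, c(aux$T0, aux$T1))
  terms <- ((unname(aux$x_T0) - xh[1, ])^2 +
            (unname(aux$x_T1) - xh[2, ])^2) / 2
  w <- rep_len(weights, system$S)
  list(value = sum(w * terms),
       terms = stats::setNames(terms, system$state_names))
}

#' Full loss breakdown at given network weights and parameters
#'
#' Evaluates all `M + 2S` weighted terms of the composite loss and their
#' total, as used during stage-two training.
#'
#' @inheritParams data_loss
#' @param tau collocation grid.
#' @param w_data,w_ode,w_aux term weights.
#' @return an object of class `sbinn_loss`.
#' @export
total_loss <- function(data, theta, p, system, tau, config,
                       w_data = 1, w_ode = 1, w_aux = 1) {
  space <- fixed_space(system, p)
  sv <- schedule_vectors(system)
  ev <- empty_events(); ev$ev_t <- sv$t; ev$ev_m <- sv$m
  prob <- make_problem(system, data, config, space, tau,
                       w_data = w_data, w_ode = w_ode, w_aux = w_aux,
                       events = ev)
  res <- eval_loss(theta, numeric(0), prob, stage = 2L, want_grad = FALSE)
  loss_breakdown(res, prob)
}
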