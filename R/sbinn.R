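# The core method: simultaneous gradient training of the trajectory
# surrogate (network weights theta) and the kinetic parameters p against the
# composite loss  L = L_data(theta) + L_ode(theta, p) + L_aux(theta).

#' Training schedule
#'
#' Two-stage full-batch Adam: stage one minimizes the supervised losses only
#' (data + auxiliary) so the surrogate quickly matches the observations;
#' stage two minimizes the full composite loss, updating the network weights
#' and the kinetic parameters simultaneously. A stage-one count of zero
#' skips the warm-up entirely.
#'
#' @param stage1,stage2 iteration counts for the two stages.
#' @param learning_rate Adam step size (constant; Adam's other
#'   hyperparameters are left at their defaults).
#' @param n_ode number of collocation points; default
#'   `max(200, 2 * n_data)`, on an equispaced grid over the training window
#'   so the residual constrains the gaps between observations.
#' @param log_every record the loss breakdown every this many iterations.
#' @param rebalance_every if positive, during stage two every this many
#'   iterations each loss weight is reset to the reciprocal of its term's
#'   current magnitude (floored relative to the largest term), keeping the
#'   weighted terms at the same order of magnitude *throughout* training.
#'   Needed when the residual scale changes by many decades as the kinetic
#'   parameters travel from their initialization to the truth (apoptosis);
#'   `0` disables it.
#' @return an object of class `sbinn_schedule`.
#' @export
sbinn_schedule <- function(stage1 = 1000, stage2 = 10000,
                           learning_rate = 1e-3, n_ode = NULL,
                           log_every = 1000, rebalance_every = 0) {
  stopifnot(stage1 >= 0, stage2 >= 0, learning_rate > 0,
            rebalance_every >= 0)
  structure(list(stage1 = as.integer(stage1), stage2 = as.integer(stage2),
                 learning_rate = learning_rate, n_ode = n_ode,
                 log_every = as.integer(log_every),
                 rebalance_every = as.integer(rebalance_every)),
            class = "sbinn_schedule")
}

#' Event-inference specification for hidden meal forcing
#'
#' For the ultradian model the exogenous forcing itself can be inferred:
#' carbohydrate masses `m_j` are trained on a log scale and meal timings
#' `t_j` through a box constraint on the training window, with a soft
#' quadratic penalty keeping the timings ordered. The number of events is
#' fixed and known.
#'
#' @param masses infer the carbohydrate content of each event.
#' @param times infer the timing of each event.
#' @param time_window box bounds for trainable timings (defaults to the
#'   training window).
#' @param order_penalty weight of the soft ordering penalty on timings.
#' @return an object of class `event_spec`.
#' @export
event_spec <- function(masses = TRUE, times = FALSE, time_window = NULL,
                       order_penalty = 1) {
  structure(list(masses = masses, times = times, time_window = time_window,
                 order_penalty = order_penalty), class = "event_spec")
}

# build the trainable-event bookkeeping; raw indices follow the model raws
build_events <- function(system, space, spec, window) {
  sv <- schedule_vectors(system)
  ev <- empty_events()
  ev$ev_t <- sv$t
  ev$ev_m <- sv$m
  nev <- length(sv$t)
  off <- space$n_raw
  raw_extra <- numeric(0)
  if (!is.null(spec) && nev > 0) {
    if (isTRUE(spec$masses)) {
      ev$m_free <- TRUE
      ev$evm_raw_idx <- off + seq_len(nev) - 1L
      off <- off + nev
      # start at the geometric mean of a plausible meal (50 g), not truth
      raw_extra <- c(raw_extra, rep(log(50), nev))
    }
    if (isTRUE(spec$times)) {
      ev$t_free <- TRUE
      tw <- if (is.null(spec$time_window)) window else spec$time_window
      ev$t_lo <- rep(tw[1], nev)
      ev$t_hi <- rep(tw[2], nev)
      ev$evt_raw_idx <- off + seq_len(nev) - 1L
      off <- off + nev
      # equispaced initial timings across the window
      tinit <- tw[1] + (seq_len(nev) / (nev + 1)) * (tw[2] - tw[1])
      raw_extra <- c(raw_extra,
                     stats::qlogis((tinit - tw[1]) / (tw[2] - tw[1])))
      ev$order_penalty <- spec$order_penalty
    }
  }
  list(events = ev, raw_extra = raw_extra)
}

#' Fit a systems-biology-informed neural network
#'
#' Trains a neural surrogate of the ODE trajectory against scattered noisy
#' observations of a subset of species, while simultaneously inferring the
#' unknown kinetic parameters (and, optionally, hidden meal forcing). The
#' loss combines the supervised data mismatch, the ODE residual evaluated
#' with the surrogate's analytic time derivative at collocation points, and
#' an auxiliary full-state term at two time instants.
#'
#' @param system an [ode_system()].
#' @param data an `sbinn_data` object from [make_dataset()] or
#'   [read_dataset()].
#' @param config an [sbinn_config()]; defaults to the benchmark architecture
#'   for built-in systems.
#' @param space a [parameter_space()]; defaults to log-positive transforms
#'   for all parameters.
#' @param schedule an [sbinn_schedule()].
#' @param w_data,w_ode,w_aux loss-term weights (default 1). The weights
#'   should keep the weighted terms at the same order of magnitude;
#'   `auto_balance` does this automatically.
#' @param auto_balance if `TRUE`, at the start of stage two each of the
#'   `M + 2S` weights is rescaled once to the reciprocal of its term's
#'   current magnitude, then frozen.
#' @param infer_events optional [event_spec()] for hidden-forcing inference
#'   (ultradian model).
#' @param seed integer seed controlling the network initialization.
#' @param verbose print the loss breakdown at each logging point.
#' @return an object of class `sbinn` with components `coefficients` (the
#'   inferred parameters on the natural scale), `theta` (network weights),
#'   `events` (inferred schedule when applicable), `history` (loss traces)
#'   and the ingredients needed by the methods.
#' @export
sbinn <- function(system, data, config = NULL, space = NULL,
                  schedule = sbinn_schedule(), w_data = 1, w_ode = 1,
                  w_aux = 1, auto_balance = FALSE, infer_events = NULL,
                  seed = 1, verbose = FALSE) {
  stopifnot(inherits(system, "ode_system"), inherits(data, "sbinn_data"))
  if (is.null(config)) config <- default_config(system)
  if (is.null(space)) space <- parameter_space(system)
  n_data <- length(data$observations$times)
  n_ode <- if (is.null(schedule$n_ode)) max(200L, 2L * n_data)
           else schedule$n_ode
  window <- range(data$design$window)
  tau <- seq(window[1], window[2], length.out = n_ode)

  evb <- build_events(system, space, infer_events, window)
  prob <- make_problem(system, data, config, space, tau,
                       w_data = rep_len(w_data,
                         length(data$observations$observable_indices)),
                       w_ode = rep_len(w_ode, system$S),
                       w_aux = rep_len(w_aux, system$S),
                       events = evb$events)

  dims <- prob$dims
  theta <- mlp_init(dims, seed = seed)
  raw <- c(space$raw_init, evb$raw_extra)
  par <- c(theta, raw)
  nth <- length(theta)

  lr <- schedule$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mom <- numeric(length(par)); vel <- numeric(length(par))
  history <- list()
  last_finite <- NULL
  it_global <- 0L

  log_state <- function(res, stage) {
    history[[length(history) + 1L]] <<- c(
      iter = it_global, stage = stage, total = res$total,
      data = sum(prob$w_data * res$data_terms),
      ode = sum(prob$w_ode * res$ode_terms),
      aux = sum(prob$w_aux * res$aux_terms))
    if (verbose)
      message(sprintf("iter %6d stage %d  total %.4e  data %.3e ode %.3e aux %.3e",
                      it_global, stage, res$total,
                      sum(prob$w_data * res$data_terms),
                      sum(prob$w_ode * res$ode_terms),
                      sum(prob$w_aux * res$aux_terms)))
  }

  rebalance <- function(res) {
    floorv <- 1e-12
    prob$w_data <<- 1 / pmax(res$data_terms, floorv)
    prob$w_ode <<- 1 / pmax(res$ode_terms, floorv)
    prob$w_aux <<- 1 / pmax(res$aux_terms, floorv)
  }

  run_stage <- function(stage, iters) {
    for (i in seq_len(iters)) {
      if (stage == 2L && schedule$rebalance_every > 0L &&
          (i - 1L) %% schedule$rebalance_every == 0L)
        rebalance(eval_loss(par[seq_len(nth)],
                            par[nth + seq_len(length(par) - nth)],
                            prob, 2L, want_grad = FALSE))
      res <- eval_loss(par[seq_len(nth)], par[nth + seq_len(length(par) - nth)],
                       prob, stage, want_grad = TRUE)
      if (!is.finite(res$total))
        stop(sprintf(
          "non-finite loss at iteration %d; last finite total was %s",
          it_global + 1L,
          if (is.null(last_finite)) "none" else format(last_finite$total)))
      last_finite <<- res
      g <- c(res$grad_theta, res$grad_raw)
      it_global <<- it_global + 1L
      mom <<- b1 * mom + (1 - b1) * g
      vel <<- b2 * vel + (1 - b2) * g^2
      mhat <- mom / (1 - b1^it_global)
      vhat <- vel / (1 - b2^it_global)
      par <<- par - lr * mhat / (sqrt(vhat) + eps)
      if (it_global %% schedule$log_every == 0L || i == iters)
        log_state(res, stage)
    }
  }

  if (schedule$stage1 > 0L) run_stage(1L, schedule$stage1)
  if (auto_balance) {
    res <- eval_loss(par[seq_len(nth)], par[nth + seq_len(length(par) - nth)],
                     prob, 2L, want_grad = FALSE)
    floorv <- 1e-12
    prob$w_data <- 1 / pmax(res$data_terms, floorv)
    prob$w_ode <- 1 / pmax(res$ode_terms, floorv)
    prob$w_aux <- 1 / pmax(res$aux_terms, floorv)
  }
  if (schedule$stage2 > 0L) run_stage(2L, schedule$stage2)

  theta <- par[seq_len(nth)]
  raw <- par[nth + seq_len(length(par) - nth)]
  res <- eval_loss(theta, raw, prob, 2L, want_grad = FALSE)
  p_hat <- stats::setNames(as.numeric(res$p), system$param_names)
  events <- NULL
  if (!is.null(system$schedule)) {
    ev_t <- as.numeric(res$ev_t); ev_m <- as.numeric(res$ev_m)
    events <- nutrition_schedule(sort(ev_t), ev_m[order(ev_t)],
                                 decay = unname(p_hat["k"]))
  }
  hist <- do.call(rbind, history)
  structure(list(
    coefficients = p_hat, theta = theta, raw = raw, events = events,
    loss = loss_breakdown(res, prob), history = hist,
    system = system, data = data, config = config, space = space,
    schedule = schedule, weights = list(data = prob$w_data, ode = prob$w_ode,
                                        aux = prob$w_aux),
    tau = tau, seed = seed, call = match.call()
  ), class = "sbinn")
}

#' @export
print.sbinn <- function(x, ...) {
  cat("Systems-biology-informed neural network fit\n")
  cat(sprintf("  system: %s | %d observations of (%s) | %d collocation points\n",
              x$system$name, length(x$data$observations$times),
              paste(x$system$state_names[x$data$observations$observable_indices],
                    collapse = ", "), length(x$tau)))
  cat(sprintf("  final loss: %.4e\n", x$loss$total))
  cat("  inferred parameters:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.sbinn <- function(object, ...) object$coefficients

#' @export
summary.sbinn <- function(object, ...) {
  free <- object$space$type != 0L
  tab <- data.frame(
    parameter = object$system$param_names,
    target = as.numeric(object$system$p_nominal),
    inferred = as.numeric(object$coefficients),
    free = free)
  tab$rel_error <- abs(tab$inferred - tab$target) / abs(tab$target)
  structure(list(table = tab, loss = object$loss, system = object$system,
                 events = object$events), class = "summary.sbinn")
}

#' @export
print.summary.sbinn <- function(x, ...) {
  cat("Parameter recovery (", x$system$name, ")\n", sep = "")
  tab <- x$table
  tab$target <- signif(tab$target, 4)
  tab$inferred <- signif(tab$inferred, 4)
  tab$rel_error <- signif(tab$rel_error, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$events)) {
    cat("inferred nutrition events (t, m):\n")
    print(data.frame(t = x$events$times, m = signif(x$events$masses, 4)),
          row.names = FALSE)
  }
  print(x$loss)
  invisible(x)
}

#' Reconstruct the full-state dynamics from a fitted surrogate
#'
#' Evaluates the trained surrogate at arbitrary query times, including for
#' species that were never observed (hidden dynamics). Queries outside the
#' training window are flagged with a warning; the surrogate is not trusted
#' there (use [forecast()] instead, which integrates the ODE with the
#' inferred parameters).
#'
#' @param object a fitted `sbinn` object.
#' @param times query times.
#' @param ... unused.
#' @return matrix `length(times) x S` with state columns.
#' @export
predict.sbinn <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$observations$times
  window <- range(object$data$design$window)
  if (any(times < window[1]) || any(times > window[2]))
    warning("query times outside the training window: surrogate extrapolation is untrusted")
  x <- surrogate_forward(object$theta, object$config, times)
  colnames(x) <- object$system$state_names
  x
}

#' @rdname predict.sbinn
#' @export
infer_dynamics <- function(object, times, ...) predict(object, times, ...)

#' @export
fitted.sbinn <- function(object, ...) {
  obs <- object$data$observations
  predict(object, obs$times)[, obs$observable_indices, drop = FALSE]
}

#' @export
residuals.sbinn <- function(object, ...) {
  object$data$observations$values - fitted(object)
}

#' @export
plot.sbinn <- function(x, times = NULL, states = NULL, ...) {
  window <- range(x$data$design$window)
  if (is.null(times)) times <- seq(window[1], window[2], length.out = 400)
  if (is.null(states)) states <- seq_len(x$system$S)
  pred <- predict(x, times)
  ref <- solve_reference(x$system, times = times)
  obs <- x$data$observations
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(states)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in states) {
    nm <- x$system$state_names[s]
    ylim <- range(ref[, s + 1], pred[, s], na.rm = TRUE)
    plot(times, ref[, s + 1], type = "l", col = "grey40", lty = 2,
         xlab = "time", ylab = nm, ylim = ylim, main = nm)
    graphics::lines(times, pred[, s], col = "firebrick")
    m <- match(s, obs$observable_indices)
    if (!is.na(m))
      graphics::points(obs$times, obs$values[, m], pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor("navy", 0.4))
  }
  invisible(x)
}

#' Forecast beyond the training window with the inferred parameters
#'
#' Integrates the ODE system from the initial condition using the inferred
#' kinetic parameters (and inferred or supplied future nutrition events),
#' which is how predictions beyond the training window are made; the
#' surrogate itself is only trusted inside the window.
#'
#' @param object a fitted `sbinn` object (or an `ode_system` with explicit
#'   parameters via the default method).
#' @param times evaluation grid, possibly extending past the training
#'   window.
#' @param future_events optional [nutrition_schedule()] of additional known
#'   future events appended to the (inferred) training-window schedule.
#' @param ... unused.
#' @return matrix with columns `time` and one per state.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' @rdname forecast
#' @export
forecast.sbinn <- function(object, times, future_events = NULL, ...) {
  system <- object$system
  p <- object$coefficients
  if (!is.null(system$schedule)) {
    sched <- if (is.null(object$events)) system$schedule else object$events
    if (!is.null(future_events)) {
      sched <- nutrition_schedule(c(sched$times, future_events$times),
                                  c(sched$masses, future_events$masses),
                                  decay = sched$decay)
    }
    system <- ultradian_model(schedule = sched)
  }
  solve_reference(system, p = p, times = times)
}
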