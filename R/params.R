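# Parameter-space transforms. Kinetic parameters are trained on an
# unconstrained raw scale; each parameter is either log-positive
# (p = exp(raw), suited to rate constants spanning many decades), box
# constrained (p = lo + (hi - lo) * sigmoid(raw), used when only a search
# range is defensible), or fixed (excluded from the gradient entirely).

#' Define the search space for the kinetic parameters
#'
#' @param system an [ode_system()].
#' @param transform default transform for free parameters: `"log"`
#'   (log-positive) or `"box"`.
#' @param lower,upper named vectors (or full-length vectors) of box bounds;
#'   by default a box parameter gets the range `(0.2 x, 1.8 x)` around its
#'   nominal value `x`.
#' @param fixed character vector of parameter names held fixed at their
#'   nominal values, or a named numeric vector of fixed values.
#' @param ref reference scales for log-positive parameters: `p = ref *
#'   exp(raw)`, so raw zero starts each parameter at its reference scale.
#'   Default 1 for every parameter; named vector to override. Use physical
#'   unit-scale priors (e.g. a diffusion-limited association constant for
#'   bimolecular rates) when rate constants live many decades below 1.
#' @param init optional named vector of initial values on the natural scale;
#'   by default the raw vector starts at zero, i.e. `p = ref` for
#'   log-positive parameters and the box midpoint for box parameters.
#' @return an object of class `parameter_space`.
#' @export
parameter_space <- function(system, transform = c("log", "box"),
                            lower = NULL, upper = NULL, fixed = NULL,
                            ref = NULL, init = NULL) {
  transform <- match.arg(transform)
  K <- system$K
  nm <- system$param_names
  p0 <- system$p_nominal
  type <- rep(if (transform == "log") 1L else 2L, K)
  pfix <- as.numeric(p0)
  lo <- 0.2 * as.numeric(p0)
  hi <- 1.8 * as.numeric(p0)
  pref <- rep(1, K)
  if (!is.null(ref)) pref[match(names(ref), nm)] <- as.numeric(ref)
  if (!is.null(lower)) lo[match(names(lower), nm)] <- lower
  if (!is.null(upper)) hi[match(names(upper), nm)] <- upper
  if (!is.null(fixed)) {
    if (is.character(fixed)) {
      type[match(fixed, nm)] <- 0L
    } else {
      type[match(names(fixed), nm)] <- 0L
      pfix[match(names(fixed), nm)] <- as.numeric(fixed)
    }
  }
  if (any(type == 2L) && any(lo[type == 2L] >= hi[type == 2L]))
    stop("box transform requires lo < hi for every boxed parameter")
  praw_idx <- rep(-1L, K)
  praw_idx[type != 0L] <- seq_len(sum(type != 0L)) - 1L   # 0-based for C++
  space <- structure(list(
    param_names = nm, type = type, pfix = pfix, lo = lo, hi = hi,
    pref = pref, praw_idx = praw_idx, n_raw = sum(type != 0L)
  ), class = "parameter_space")
  space$raw_init <- if (is.null(init)) numeric(space$n_raw)
                    else inverse_transform(init, space, default = 0)
  space
}

#' Map raw (unconstrained) trainables to natural parameter values
#'
#' @param raw numeric vector of length `n_raw`.
#' @param space a [parameter_space()].
#' @return named numeric vector of all `K` parameters on the natural scale.
#' @export
transform_params <- function(raw, space) {
  stopifnot(inherits(space, "parameter_space"), length(raw) == space$n_raw)
  p <- space$pfix
  free <- space$type != 0L
  r <- raw[space$praw_idx[free] + 1L]
  p[free] <- ifelse(space$type[free] == 1L, space$pref[free] * exp(r),
                    space$lo[free] + (space$hi[free] - space$lo[free]) *
                      stats::plogis(r))
  stats::setNames(p, space$param_names)
}

#' @rdname transform_params
#' @param p named vector of natural-scale values (subset allowed).
#' @param default raw value used for free parameters not named in `p`.
#' @export
inverse_transform <- function(p, space, default = 0) {
  raw <- rep(as.numeric(default), space$n_raw)
  for (nmi in names(p)) {
    k <- match(nmi, space$param_names)
    if (is.na(k) || space$type[k] == 0L) next
    raw[space$praw_idx[k] + 1L] <-
      if (space$type[k] == 1L) log(p[[nmi]] / space$pref[k])
      else stats::qlogis((p[[nmi]] - space$lo[k]) / (space$hi[k] - space$lo[k]))
  }
  raw
}

#' @export
print.parameter_space <- function(x, ...) {
  lab <- c("fixed", "log-positive", "box")[x$type + 1L]
  df <- data.frame(parameter = x$param_names, transform = lab,
                   fixed_value = ifelse(x$type == 0L, x$pfix, NA),
                   lower = ifelse(x$type == 2L, x$lo, NA),
                   upper = ifelse(x$type == 2L, x$hi, NA))
  cat(sprintf("parameter_space: %d free of %d parameters\n", x$n_raw,
              length(x$param_names)))
  print(df, row.names = FALSE)
  invisible(x)
}
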