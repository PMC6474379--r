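#' Atomic signed measures on the knot domain
#'
#' An `atomic_measure` is a finitely supported signed measure on
#' `{1..D} x [0,1]`.  It plays the role of the second derivative of a
#' degree-one saturating spline: each atom `(coord, t, w)` is a knot at
#' location `t` (in scaled feature space) on feature `coord`, and the
#' spline's slope on that coordinate jumps by `w` at `t`.  Saturation of
#' the spline corresponds to the measure having zero net mass on every
#' coordinate; the total-variation budget of the fit is the l1 norm
#' `sum(|w|)` of the weights.
#'
#' @param atoms data.frame with numeric columns `coord` (1-based feature
#'   index), `t` (knot location in `[0,1]`) and `w` (signed weight).
#'   Atoms sharing an exact `(coord, t)` pair are merged by weight
#'   summation.
#' @param D number of coordinates (features).
#' @return an object of class `atomic_measure`: a list with elements
#'   `atoms` (canonically ordered data.frame) and `D`.
#' @examples
#' mu <- atomic_measure(data.frame(coord = 1, t = c(.25, .75), w = c(1, -1)), D = 1)
#' tv_norm(mu)      # 2
#' net_mass(mu, 1)  # 0
#' @export
atomic_measure <- function(atoms = empty_atoms(), D = 1L) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 1L) stop("D must be a positive integer")
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) == 0L) atoms <- empty_atoms()
  required <- c("coord", "t", "w")
  if (!all(required %in% names(atoms))) {
    stop("atoms must have columns coord, t, w")
  }
  atoms <- atoms[required]
  atoms$coord <- as.integer(atoms$coord)
  atoms$t <- as.numeric(atoms$t)
  atoms$w <- as.numeric(atoms$w)
  if (nrow(atoms)) {
    if (anyNA(atoms) || any(!is.finite(atoms$w)) || any(!is.finite(atoms$t))) {
      stop("atoms must be finite")
    }
    if (any(atoms$coord < 1L | atoms$coord > D)) stop("atom coord out of range 1..D")
    if (any(atoms$t < 0 | atoms$t > 1)) stop("atom locations must lie in [0,1]")
  }
  m <- structure(list(atoms = atoms, D = D), class = "atomic_measure")
  prune_merge(m, w_tol = 0)
}

empty_atoms <- function() {
  data.frame(coord = integer(0), t = numeric(0), w = numeric(0))
}

#' @export
print.atomic_measure <- function(x, ...) {
  cat(sprintf("<atomic_measure> D=%d, %d atom(s), TV=%g\n",
              x$D, nrow(x$atoms), tv_norm(x)))
  if (nrow(x$atoms)) print(x$atoms, row.names = FALSE)
  invisible(x)
}

#' Total variation of an atomic measure
#'
#' `sum(|w|)` over the atoms; equal to the total variation of the
#' derivative of the associated spline, i.e. the l1 norm of its second
#' derivative.
#'
#' @param measure an [atomic_measure()].
#' @return nonnegative scalar.
#' @export
tv_norm <- function(measure) {
  stopifnot(inherits(measure, "atomic_measure"))
  sum(abs(measure$atoms$w))
}

#' Net mass of an atomic measure on one coordinate
#'
#' Saturating splines require this to be zero for every coordinate: a
#' nonzero net mass would leave a linear trend beyond the largest knot.
#'
#' @param measure an [atomic_measure()].
#' @param coord 1-based feature index.
#' @return signed scalar (0 for coordinates without atoms).
#' @export
net_mass <- function(measure, coord) {
  stopifnot(inherits(measure, "atomic_measure"))
  coord <- as.integer(coord)
  if (length(coord) != 1L || is.na(coord) || coord < 1L || coord > measure$D) {
    stop("coord out of range 1..D")
  }
  sum(measure$atoms$w[measure$atoms$coord == coord])
}

#' Merge duplicate knots and drop negligible atoms
#'
#' Atoms with identical `(coord, t)` are merged by weight summation, then
#' atoms with `|w| <= w_tol` are removed.  Idempotent; the result is
#' canonically ordered by `(coord, t)`.
#'
#' @param measure an [atomic_measure()].
#' @param w_tol nonnegative weight threshold.
#' @return a cleaned `atomic_measure`.
#' @export
prune_merge <- function(measure, w_tol = 0) {
  stopifnot(inherits(measure, "atomic_measure"))
  if (length(w_tol) != 1L || is.na(w_tol) || w_tol < 0) stop("w_tol must be >= 0")
  a <- measure$atoms
  if (nrow(a)) {
    key <- paste(a$coord, format(a$t, digits = 22), sep = "@")
    if (anyDuplicated(key)) {
      w <- tapply(a$w, key, sum)
      first <- !duplicated(key)
      a <- a[first, , drop = FALSE]
      a$w <- as.numeric(w[paste(a$coord, format(a$t, digits = 22), sep = "@")])
    }
    a <- a[abs(a$w) > w_tol, , drop = FALSE]
    a <- a[order(a$coord, a$t), , drop = FALSE]
    rownames(a) <- NULL
  }
  structure(list(atoms = a, D = measure$D), class = "atomic_measure")
}

#' Hinge basis column for a knot
#'
#' Evaluates the hinge function `x -> (x - t)_+` of a knot at `t` on
#' feature `coord` over all rows of a scaled design matrix.
#'
#' @param t knot location in `[0,1]`.
#' @param coord 1-based feature index.
#' @param X numeric matrix (n x D) of scaled features.
#' @return n-vector of nonnegative hinge values, nonincreasing in `t`.
#' @export
eval_basis <- function(t, coord, X) {
  X <- as.matrix(X)
  coord <- as.integer(coord)
  if (length(coord) != 1L || is.na(coord) || coord < 1L || coord > ncol(X)) {
    stop("coord out of range 1..D")
  }
  if (length(t) != 1L || !is.finite(t)) stop("t must be a finite scalar")
  pmax(X[, coord] - t, 0)
}

#' Saturating spline model
#'
#' A fitted (or hand-built) saturating spline: intercept `c` plus the
#' double integral of an atomic measure, evaluated through a stored
#' per-coordinate affine scaling that maps raw features into `[0,1]`.
#' Because every hinge vanishes at scaled 0 and the per-coordinate net
#' mass is zero, predictions are exactly constant outside the training
#' range: `f(x) = f(0)` below and `f(x) = f(1)` above, per coordinate.
#'
#' @param measure an [atomic_measure()].
#' @param intercept scalar offset (response scale); the value of the
#'   fitted function at scaled 0 on all coordinates.
#' @param scaling data.frame with columns `shift`, `range` (one row per
#'   coordinate): scaled value is `(x - shift)/range`; a zero `range`
#'   marks a constant training column, mapped to the constant 0.5.
#' @param tau total-variation budget used in fitting (for reporting).
#' @param loss the [loss_spec()] used in fitting, or NULL.
#' @param gap duality-gap certificate attached by the fitting loop.
#' @return object of class `spline_model`.
#' @export
spline_model <- function(measure, intercept = 0,
                         scaling = data.frame(shift = rep(0, measure$D),
                                              range = rep(1, measure$D)),
                         tau = NULL, loss = NULL, gap = NA_real_) {
  stopifnot(inherits(measure, "atomic_measure"))
  scaling <- as.data.frame(scaling)
  if (!all(c("shift", "range") %in% names(scaling))) {
    stop("scaling must have columns shift, range")
  }
  if (nrow(scaling) != measure$D) stop("scaling must have one row per coordinate")
  if (length(intercept) != 1L || !is.finite(intercept)) stop("intercept must be finite")
  structure(list(measure = measure, intercept = as.numeric(intercept),
                 scaling = scaling[c("shift", "range")], tau = tau,
                 loss = loss, gap = gap),
            class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("<spline_model> D=%d, %d knot(s), intercept=%g, TV=%g",
              x$measure$D, nrow(x$measure$atoms), x$intercept, tv_norm(x$measure)))
  if (!is.null(x$tau)) cat(sprintf(", tau=%g", x$tau))
  cat("\n")
  invisible(x)
}

#' Evaluate a saturating spline at raw feature values
#'
#' @param model a [spline_model()].
#' @param X_raw numeric matrix or data.frame (n x D) of raw features; may
#'   lie outside the training range (the spline saturates there).
#' @return n-vector of predictions.
#' @export
eval_spline <- function(model, X_raw) {
  stopifnot(inherits(model, "spline_model"))
  X_raw <- as.matrix(X_raw)
  if (ncol(X_raw) != model$measure$D) {
    stop(sprintf("X has %d columns, model expects %d", ncol(X_raw), model$measure$D))
  }
  Xs <- scale_apply(model$scaling, X_raw)
  preds <- rep(model$intercept, nrow(Xs))
  a <- model$measure$atoms
  for (k in seq_len(nrow(a))) {
    preds <- preds + a$w[k] * pmax(Xs[, a$coord[k]] - a$t[k], 0)
  }
  preds
}

#' @param object a [spline_model()].
#' @param newdata raw feature matrix/data.frame.
#' @param ... unused.
#' @rdname eval_spline
#' @export
predict.spline_model <- function(object, newdata, ...) {
  eval_spline(object, newdata)
}

#' Coordinates carrying at least one knot
#'
#' A coordinate with no atoms contributes the constant 0 and is "out of
#' the model" -- the feature-selection readout of a saturating-spline GAM.
#'
#' @param model a [spline_model()].
#' @return sorted integer vector of active (selected) coordinates.
#' @export
active_coords <- function(model) {
  stopifnot(inherits(model, "spline_model"))
  sort(unique(model$measure$atoms$coord))
}

# Validate the saturating-spline invariants (used by tests and fitting).
# Returns TRUE or a character description of the first violation.
check_model_invariants <- function(model, tau = model$tau) {
  m <- model$measure
  tv <- tv_norm(m)
  if (!is.null(tau) && tv > tau * (1 + 1e-9)) {
    return(sprintf("TV %g exceeds budget %g", tv, tau))
  }
  for (d in seq_len(m$D)) {
    nm <- net_mass(m, d)
    if (abs(nm) > 1e-9 * max(1, tv)) {
      return(sprintf("net mass %g on coordinate %d", nm, d))
    }
  }
  TRUE
}
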