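#' Options for the outer fitting loop
#'
#' @param tau nonnegative total-variation budget (`tau = 0` fits the best
#'   constant).
#' @param max_outer outer (knot-adding) iteration cap.
#' @param tol_gap relative duality-gap stopping tolerance: stop when
#'   `gap <= tol_gap * max(1, |objective|)`.
#' @param tol_inner relative Frank-Wolfe gap tolerance of the corrective
#'   step.
#' @param w_tol weight-pruning threshold; default `1e-8 * tau`.
#' @param refine run discrete knot-location refinement after convergence.
#' @param seed unused by the deterministic default algorithm; reserved for
#'   stochastic refinement variants.
#' @param max_inner iteration cap of the corrective solver.
#' @param quiet suppress per-iteration progress messages.
#' @return list of class `fit_options`.
#' @export
fit_options <- function(tau = 1, max_outer = 500L, tol_gap = 1e-6,
                        tol_inner = 1e-8, w_tol = NULL, refine = FALSE,
                        seed = NULL, max_inner = 10000L, quiet = TRUE) {
  if (length(tau) != 1L || !is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (tol_gap <= 0 || tol_inner <= 0) stop("tolerances must be > 0")
  if (max_outer < 1L) stop("max_outer must be >= 1")
  if (!is.null(w_tol) && (w_tol < 0)) stop("w_tol must be >= 0")
  structure(list(tau = tau, max_outer = as.integer(max_outer),
                 tol_gap = tol_gap, tol_inner = tol_inner,
                 w_tol = if (is.null(w_tol)) 1e-8 * tau else w_tol,
                 refine = isTRUE(refine), seed = seed,
                 max_inner = as.integer(max_inner), quiet = isTRUE(quiet)),
            class = "fit_options")
}

# Restore exact per-coordinate zero net mass by setting the weight of
# each coordinate's zero-basis-column "slack" knot (at the scaled
# maximum) to minus the sum of the others.  Predictions are unchanged
# because the slack columns are identically zero on the training data.
rebalance_slack <- function(knots, w, slack_t) {
  for (d in unique(knots$coord)) {
    in_g <- which(knots$coord == d)
    sl <- in_g[knots$t[in_g] == slack_t[d]]
    others <- setdiff(in_g, sl)
    target <- -sum(w[others])
    if (length(sl)) {
      w[sl[1]] <- target
    } else if (target != 0) {
      knots <- rbind(knots, data.frame(coord = d, t = slack_t[d]))
      w <- c(w, target)
    }
  }
  list(knots = knots, w = w)
}

# Threshold-prune small weights, then restore exact per-coordinate
# zero net mass through the zero-basis-column "slack" knot at the scaled
# maximum of each coordinate.  The prune is only accepted if it does not
# increase the objective, so the outer objective trace is exactly
# monotone.  Returns list(knots, w, z, changed).
prune_rebalance <- function(knots, w, Xs, z, cc, y, loss, w_tol, obj_now,
                            slack_t) {
  keep <- abs(w) > w_tol
  if (all(keep)) return(list(knots = knots, w = w, z = z, changed = FALSE))
  rb <- rebalance_slack(knots[keep, , drop = FALSE], w[keep], slack_t)
  k2 <- rb$knots[rb$w != 0, , drop = FALSE]
  w2 <- rb$w[rb$w != 0]
  z2 <- rep(cc, nrow(Xs))
  for (k in seq_len(nrow(k2))) {
    z2 <- z2 + w2[k] * pmax(Xs[, k2$coord[k]] - k2$t[k], 0)
  }
  obj2 <- dataset_loss_grad(loss, z2, y)$value
  if (obj2 <= obj_now) {
    rownames(k2) <- NULL
    list(knots = k2, w = w2, z = z2, changed = TRUE)
  } else {
    list(knots = knots, w = w, z = z, changed = FALSE)
  }
}

#' Fit a saturating-spline generalized additive model
#'
#' Outer fully-corrective conditional gradient loop: scale features onto
#' `[0,1]`; repeatedly (i) evaluate the loss gradient at the current
#' predictions, (ii) call the exact linear minimization oracle for the
#' best two-point measure and the duality-gap certificate, (iii) stop if
#' the gap is below tolerance, else add the knot pair and re-solve all
#' weights (and the intercept) with the pairwise Frank-Wolfe corrective
#' step, then prune negligible knots.  Every returned model saturates,
#' has per-coordinate net mass zero, and `TV <= tau`; `final_gap` bounds
#' its true suboptimality for the measure-space problem.
#'
#' @param X n x D matrix/data.frame of raw features.
#' @param y n-vector of responses (`{-1,+1}` for logistic loss).
#' @param loss a [loss_spec()].
#' @param options a [fit_options()] (carries `tau`).
#' @param warm optional warm start: a `spline_model` fitted on the same
#'   training matrix (used by [fit_path()]); its measure must be feasible
#'   for the current budget.
#' @return object of class `satspline_fit`: list with `model`
#'   ([spline_model()]), `trace` (data.frame `iter`, `objective`, `gap`,
#'   `knots`), `converged`, `final_gap`.
#' @export
fit_gam <- function(X, y, loss = loss_spec("squared"),
                    options = fit_options(), warm = NULL) {
  stopifnot(inherits(options, "fit_options"), inherits(loss, "loss_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); D <- ncol(X)
  if (n < 1L || D < 1L) stop("need at least one row and one column")
  if (length(y) != n) stop("y length must match rows of X")
  if (any(!is.finite(y))) stop("nonfinite responses")
  tau <- options$tau
  sd_ <- scale_fit_transform(X)
  Xs <- sd_$X_scaled
  slack_t <- apply(Xs, 2, max)

  knots <- data.frame(coord = integer(0), t = numeric(0))
  w <- numeric(0)
  cc <- 0
  if (!is.null(warm)) {
    stopifnot(inherits(warm, "spline_model"))
    a <- warm$measure$atoms
    if (nrow(a)) {
      knots <- data.frame(coord = a$coord, t = a$t)
      w <- a$w
    }
    cc <- warm$intercept
  }
  build_basis <- function(kn) {
    B <- matrix(0, n, nrow(kn))
    for (k in seq_len(nrow(kn))) B[, k] <- pmax(Xs[, kn$coord[k]] - kn$t[k], 0)
    B
  }
  z <- if (nrow(knots)) drop(build_basis(knots) %*% w) + cc else rep(cc, n)
  dc <- solve_intercept_shift(loss, z, y)
  z <- z + dc; cc <- cc + dc

  if (tau == 0) {
    lg <- dataset_loss_grad(loss, z, y)
    model <- spline_model(atomic_measure(D = D), cc, sd_$transforms,
                          tau = tau, loss = loss, gap = 0)
    return(structure(list(model = model,
                          trace = data.frame(iter = 0L, objective = lg$value,
                                             gap = 0, knots = 0L),
                          converged = TRUE, final_gap = 0, loss = loss,
                          options = options, feature_names = sd_$feature_names),
                     class = "satspline_fit"))
  }

  tr_iter <- integer(0); tr_obj <- numeric(0); tr_gap <- numeric(0)
  tr_kn <- integer(0)
  m <- 0L
  converged <- FALSE
  gap <- NA_real_
  repeat {
    lg <- dataset_loss_grad(loss, z, y)
    obj <- lg$value
    lmo <- lmo_gam(lg$grad, Xs, tau)
    gap <- duality_gap(lg$grad, z - cc, lmo)
    tr_iter <- c(tr_iter, m); tr_obj <- c(tr_obj, obj)
    tr_gap <- c(tr_gap, gap); tr_kn <- c(tr_kn, nrow(knots))
    if (!options$quiet) {
      message(sprintf("outer %3d  obj %.8g  gap %.3g  knots %d",
                      m, obj, gap, nrow(knots)))
    }
    converged <- lmo$optimal_flag || gap <= options$tol_gap * max(1, abs(obj))
    if (converged || m >= options$max_outer) break
    m <- m + 1L
    for (tt in unique(c(lmo$t_plus, lmo$t_minus))) {
      if (!any(knots$coord == lmo$coord & knots$t == tt)) {
        knots <- rbind(knots, data.frame(coord = lmo$coord, t = tt))
        w <- c(w, 0)
      }
    }
    prob <- structure(list(knots = knots, basis = build_basis(knots),
                           tau = tau, groups = as.integer(knots$coord)),
                      class = "restricted_problem")
    rs <- restricted_solve(prob, y, loss, w0 = w, c0 = cc,
                           tol_inner = options$tol_inner,
                           max_inner = options$max_inner, z0 = z)
    w <- rs$w; cc <- rs$c; z <- rs$z
    pr <- prune_rebalance(knots, w, Xs, z, cc, y, loss, options$w_tol,
                          rs$obj, slack_t)
    knots <- pr$knots; w <- pr$w; z <- pr$z
  }

  rb <- rebalance_slack(knots, w, slack_t)  # exact saturation, free
  meas <- atomic_measure(data.frame(coord = rb$knots$coord, t = rb$knots$t,
                                    w = rb$w), D = D)
  model <- spline_model(meas, cc, sd_$transforms, tau = tau, loss = loss,
                        gap = gap)
  fit <- structure(list(model = model,
                        trace = data.frame(iter = tr_iter, objective = tr_obj,
                                           gap = tr_gap, knots = tr_kn),
                        converged = converged, final_gap = gap, loss = loss,
                        options = options, feature_names = sd_$feature_names),
                   class = "satspline_fit")
  if (options$refine) {
    fit <- refine_fit(fit, X, y, loss, options)
  }
  fit
}

#' Fit a univariate saturating spline
#'
#' The D = 1 case of [fit_gam()]; the trace and model are identical to
#' calling [fit_gam()] on a one-column matrix.
#'
#' @param x n-vector of raw feature values.
#' @inheritParams fit_gam
#' @return a `satspline_fit` (see [fit_gam()]).
#' @export
fit_univariate <- function(x, y, loss = loss_spec("squared"),
                           options = fit_options()) {
  fit_gam(matrix(as.numeric(x), ncol = 1), y, loss, options)
}

#' @export
print.satspline_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<satspline_fit> tau=%g  objective=%.6g  gap=%.3g  knots=%d  %s\n",
              x$options$tau, last$objective, x$final_gap,
              nrow(x$model$measure$atoms),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @param object a `satspline_fit`.
#' @param newdata raw feature matrix.
#' @param ... unused.
#' @rdname fit_gam
#' @export
predict.satspline_fit <- function(object, newdata, ...) {
  eval_spline(object$model, newdata)
}

#' Warm-started regularization path
#'
#' Fits over a strictly increasing budget grid, warm-starting each fit
#' from the previous solution (feasible because the budgets nest).  Each
#' per-tau fit carries its own duality-gap certificate, and the training
#' objective is nonincreasing along the path.
#'
#' @inheritParams fit_gam
#' @param taus strictly increasing nonnegative budgets; default
#'   [default_tau_grid()].
#' @return object of class `satspline_path`: list with `taus`, `fits`,
#'   and a `summary` data.frame (`tau`, `objective`, `gap`, `n_knots`,
#'   `n_active_features`).
#' @export
fit_path <- function(X, y, loss = loss_spec("squared"), taus = NULL,
                     options = fit_options()) {
  X <- as.matrix(X)
  if (is.null(taus)) taus <- default_tau_grid(X, y)
  if (any(!is.finite(taus)) || any(taus < 0)) stop("taus must be nonnegative")
  if (is.unsorted(taus, strictly = TRUE)) stop("taus must be strictly increasing")
  fits <- vector("list", length(taus))
  warm <- NULL
  for (k in seq_along(taus)) {
    ok <- options
    ok$tau <- taus[k]
    ok$w_tol <- 1e-8 * max(taus[k], 1e-300)
    fits[[k]] <- fit_gam(X, y, loss, ok, warm = warm)
    warm <- fits[[k]]$model
  }
  summary <- data.frame(
    tau = taus,
    objective = vapply(fits, function(f) f$trace$objective[nrow(f$trace)], 0),
    gap = vapply(fits, function(f) f$final_gap, 0),
    n_knots = vapply(fits, function(f) nrow(f$model$measure$atoms), 0L),
    n_active_features = vapply(fits, function(f) length(active_coords(f$model)), 0L)
  )
  structure(list(taus = taus, fits = fits, summary = summary),
            class = "satspline_path")
}

#' @export
print.satspline_path <- function(x, ...) {
  cat(sprintf("<satspline_path> %d budgets in [%g, %g]\n",
              length(x$taus), min(x$taus), max(x$taus)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Total variation of the interpolant's derivative
#'
#' TV of the derivative of the piecewise-linear interpolant through
#' `(x, y)` (duplicated `x` values are averaged), extended flat outside
#' the data range, so the boundary slopes contribute `|s_first|` and
#' `|s_last|`.  Any saturating spline with budget at least this value can
#' interpolate the data exactly.  With `smooth_window = k > 1` the sorted
#' points are first aggregated into blocks of `k` consecutive points
#' (means of both `x` and `y`), giving a noise-robust *estimate* of the
#' underlying signal's TV: the raw interpolant TV blows up like
#' n^2 * noise through near-duplicate `x` values, which would mis-centre
#' the default budget grid.
#'
#' @param x,y numeric vectors.
#' @param smooth_window NULL (exact interpolant) or an integer block size.
#' @return nonnegative scalar.
#' @export
tv_interpolant <- function(x, y, smooth_window = NULL) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  if (!is.null(smooth_window) && smooth_window > 1L) {
    blk <- (seq_along(xs) - 1L) %/% as.integer(smooth_window)
    xs2 <- as.numeric(tapply(xs, blk, mean))
    ys <- as.numeric(tapply(ys, blk, mean))
    xs <- xs2
  }
  if (anyDuplicated(xs)) {
    ys <- as.numeric(tapply(ys, match(xs, xs), mean))
    xs <- unique(xs)
  }
  if (length(xs) < 2L) return(0)
  s <- diff(ys) / diff(xs)
  abs(s[1]) + sum(abs(diff(s))) + abs(s[length(s)])
}

#' Default geometric budget grid
#'
#' Upper end: twice the largest per-coordinate TV estimate of the
#' (presmoothed) interpolant derivative; lower end: upper / 1000;
#' `n_taus` geometrically spaced points.
#'
#' @param X raw feature matrix.
#' @param y responses.
#' @param n_taus number of grid points (default 16).
#' @return increasing numeric vector of budgets.
#' @export
default_tau_grid <- function(X, y, n_taus = 16L) {
  X <- as.matrix(X)
  win <- max(1L, as.integer(ceiling(nrow(X) / 25)))
  tvs <- apply(X, 2, function(col) tv_interpolant(col, y, smooth_window = win))
  upper <- 2 * max(tvs, 0)
  if (upper <= 0) upper <- 1
  exp(seq(log(upper / 1000), log(upper), length.out = n_taus))
}

#' Discrete knot-location refinement
#'
#' Proposes moving each knot to the adjacent candidate locations of its
#' coordinate (neighbouring data values), re-solving the weights, and
#' accepts only moves that do not increase the objective.  Optional: the
#' outer loop converges without it, but refinement can improve the
#' objective and sparsity at fixed support size.
#'
#' @param model a fitted [spline_model()].
#' @param X raw training features the model was fitted on.
#' @param y training responses.
#' @param loss a [loss_spec()].
#' @param options a [fit_options()] (inner tolerances are reused).
#' @return a `spline_model` with objective no worse than the input's.
#' @export
refine_knots <- function(model, X, y, loss = loss_spec("squared"),
                         options = fit_options(tau = model$tau)) {
  stopifnot(inherits(model, "spline_model"))
  X <- as.matrix(X)
  Xs <- scale_apply(model$scaling, X)
  tau <- if (is.null(model$tau)) tv_norm(model$measure) else model$tau
  a <- model$measure$atoms
  if (!nrow(a)) return(model)
  knots <- data.frame(coord = a$coord, t = a$t)
  w <- a$w
  cc <- model$intercept
  cand <- lapply(seq_len(ncol(Xs)), function(d) candidate_knots(Xs[, d]))
  eval_obj <- function(kn, ww, c0) {
    z <- rep(c0, nrow(Xs))
    for (k in seq_len(nrow(kn))) {
      z <- z + ww[k] * pmax(Xs[, kn$coord[k]] - kn$t[k], 0)
    }
    dataset_loss_grad(loss, z, y)$value
  }
  obj <- eval_obj(knots, w, cc)
  for (k in seq_len(nrow(knots))) {
    cd <- cand[[knots$coord[k]]]
    pos <- findInterval(knots$t[k], cd)
    for (tt in cd[c(pos - 1L, pos + 1L)[c(pos - 1L, pos + 1L) >= 1 &
                                        c(pos - 1L, pos + 1L) <= length(cd)]]) {
      if (any(knots$coord == knots$coord[k] & knots$t == tt)) next
      kn2 <- knots; kn2$t[k] <- tt
      prob <- restricted_problem(kn2, Xs, tau)
      rs <- restricted_solve(prob, y, loss, w0 = w, c0 = cc,
                             tol_inner = options$tol_inner,
                             max_inner = options$max_inner)
      if (rs$obj <= obj) {
        knots <- kn2; w <- rs$w; cc <- rs$c; obj <- rs$obj
      }
    }
  }
  meas <- atomic_measure(data.frame(coord = knots$coord, t = knots$t, w = w),
                         D = model$measure$D)
  spline_model(meas, cc, model$scaling, tau = model$tau, loss = loss,
               gap = model$gap)
}

# Apply refinement inside fit_gam and recompute the certificate.
refine_fit <- function(fit, X, y, loss, options) {
  model <- refine_knots(fit$model, X, y, loss, options)
  Xs <- scale_apply(model$scaling, as.matrix(X))
  z <- eval_spline(model, as.matrix(X))
  lg <- dataset_loss_grad(loss, z, y)
  lmo <- lmo_gam(lg$grad, Xs, options$tau)
  gap <- duality_gap(lg$grad, z - model$intercept, lmo)
  model$gap <- gap
  fit$model <- model
  fit$final_gap <- gap
  fit
}
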