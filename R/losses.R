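#' Pointwise loss specification
#'
#' Convex, differentiable pointwise losses `l(z, y)` in the prediction
#' `z`:
#' \describe{
#'   \item{squared}{`(z - y)^2 / 2`, standard regression.}
#'   \item{logistic}{`log(1 + exp(-z*y))` with labels `y` in `{-1, +1}`,
#'     computed in overflow-safe softplus form.}
#'   \item{pseudo_huber}{`delta * (sqrt(1 + u^2/delta) - 1)` with residual
#'     `u = z - y`: quadratic (`u^2/2`) for `|u| << sqrt(delta)` and
#'     linear with slope `sqrt(delta)` for `|u| >> sqrt(delta)`.  With the
#'     default `delta = 0.0015` the quadratic-to-linear transition scale
#'     is `sqrt(delta) = 0.0387 ~ 0.039`.}
#' }
#'
#' @param kind one of `"squared"`, `"logistic"`, `"pseudo_huber"`.
#' @param delta positive transition parameter (pseudo_huber only).
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(kind = c("squared", "logistic", "pseudo_huber"),
                      delta = 0.0015) {
  kind <- match.arg(kind)
  if (kind == "pseudo_huber") {
    if (length(delta) != 1L || !is.finite(delta) || delta <= 0) {
      stop("delta must be a positive scalar")
    }
  } else {
    delta <- NULL
  }
  structure(list(kind = kind, delta = delta), class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf("<loss_spec> %s%s\n", x$kind,
              if (is.null(x$delta)) "" else sprintf(" (delta=%g)", x$delta)))
  invisible(x)
}

#' Loss value and derivative at predictions
#'
#' Vectorized over `(z, y)` pairs.
#'
#' @param spec a [loss_spec()].
#' @param z numeric vector of predictions.
#' @param y numeric vector of responses (`{-1,+1}` for logistic), recycled
#'   against `z` if scalar.
#' @return list with numeric vectors `value` and `grad` (`d value / d z`).
#' @export
loss_value_grad <- function(spec, z, y) {
  stopifnot(inherits(spec, "loss_spec"))
  if (any(!is.finite(z))) stop("nonfinite predictions passed to loss")
  if (any(!is.finite(y))) stop("nonfinite responses passed to loss")
  if (length(y) == 1L) y <- rep(y, length(z))
  if (length(z) != length(y)) stop("z and y lengths differ")
  switch(spec$kind,
    squared = {
      r <- z - y
      list(value = 0.5 * r^2, grad = r)
    },
    logistic = {
      if (!all(y %in% c(-1, 1))) stop("logistic loss requires labels in {-1, +1}")
      m <- z * y
      # softplus(-m) = log(1 + exp(-m)), stable for large |m|
      value <- pmax(-m, 0) + log1p(exp(-abs(m)))
      grad <- -y * stats::plogis(-m)   # -y / (1 + exp(z*y))
      list(value = value, grad = grad)
    },
    pseudo_huber = {
      u <- z - y
      r <- sqrt(1 + u^2 / spec$delta)
      # delta*(r - 1) rewritten as u^2/(1 + r): same value, no
      # cancellation for |u| << sqrt(delta)
      list(value = u^2 / (1 + r), grad = u / r)
    }
  )
}

#' Dataset loss and gradient
#'
#' Total loss `L = sum_i l(z_i, y_i)` and its gradient with respect to
#' the prediction vector.  For squared loss the gradient is the residual
#' `z - y`; in general it is the vector `g` the linear minimization
#' oracle correlates against the hinge basis.
#'
#' @param spec a [loss_spec()].
#' @param z n-vector of predictions.
#' @param y n-vector of responses.
#' @return list with scalar `value` and n-vector `grad`.
#' @export
dataset_loss_grad <- function(spec, z, y) {
  if (length(z) != length(y)) stop("z and y lengths differ")
  vg <- loss_value_grad(spec, z, y)
  list(value = sum(vg$value), grad = vg$grad)
}

# Exact 1-D minimization of sum_i l(z0_i + dc, y_i) over the intercept
# shift dc.  Closed form for squared loss; safeguarded Newton (with
# bisection fallback) otherwise.  Returns the shift dc.
solve_intercept_shift <- function(spec, z0, y, tol = 1e-12, max_iter = 200L) {
  if (spec$kind == "squared") return(mean(y - z0))
  dphi <- function(dc) sum(loss_value_grad(spec, z0 + dc, y)$grad)
  d2_bound <- switch(spec$kind, logistic = 0.25, pseudo_huber = 1, 1)
  # bracket a sign change
  lo <- -1; hi <- 1
  flo <- dphi(lo); fhi <- dphi(hi)
  expand <- 0L
  while (flo > 0 && expand < 80L) { lo <- lo * 2; flo <- dphi(lo); expand <- expand + 1L }
  while (fhi < 0 && expand < 160L) { hi <- hi * 2; fhi <- dphi(hi); expand <- expand + 1L }
  if (flo > 0 || fhi < 0) {
    # monotone losses with separable data (e.g. all labels equal): the
    # unconstrained minimizer is at infinity; cap at the bracket edge.
    return(if (abs(flo) < abs(fhi)) lo else hi)
  }
  x <- 0
  if (x < lo || x > hi) x <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    fx <- dphi(x)
    if (abs(fx) <= tol * max(1, length(y) * d2_bound)) break
    if (fx > 0) hi <- x else lo <- x
    # Newton step using a curvature estimate by finite difference
    h <- max(1e-7, 1e-7 * abs(x))
    curv <- (dphi(x + h) - fx) / h
    xn <- if (is.finite(curv) && curv > 0) x - fx / curv else NA_real_
    x <- if (is.finite(xn) && xn > lo && xn < hi) xn else (lo + hi) / 2
    if (hi - lo < 1e-15 * max(1, abs(x))) break
  }
  x
}

# Loss-specific curvature upper bound (Lipschitz constant of the
# pointwise gradient), used for step sizes in the reference solver.
loss_curvature_bound <- function(spec) {
  switch(spec$kind, squared = 1, logistic = 0.25, pseudo_huber = 1)
}
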