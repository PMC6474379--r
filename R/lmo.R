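#' Hinge correlation profile over candidate knots
#'
#' Evaluates `h(t) = sum_{i: x_i >= t} g_i * (x_i - t)`, the inner
#' product of the loss gradient `g` with the hinge basis column at `t`,
#' at every candidate knot.  `h` is piecewise linear in `t` with
#' breakpoints exactly at the data points and is identically 0 for
#' `t >= max(x)`, so its extrema over `[0,1]` are attained on the
#' candidate set `{0} U {x_i}`.  Computed in a single pass via suffix
#' sums of `g` and `g*x`.
#'
#' @param g n-vector (loss gradient at the current predictions), ordered
#'   to match `x_sorted`.
#' @param x_sorted n-vector of feature values sorted ascending.
#' @param candidates ascending vector of candidate knot locations
#'   (default `{0} U {x_i}`, deduplicated).
#' @return numeric vector of `h` values at the candidates.
#' @export
hinge_score_profile <- function(g, x_sorted,
                                candidates = candidate_knots(x_sorted)) {
  n <- length(x_sorted)
  if (n == 0L) stop("empty feature vector")
  if (length(g) != n) stop("g and x lengths differ")
  if (is.unsorted(x_sorted)) stop("x must be sorted ascending")
  # suffix sums over atoms with x_i >= t
  s0 <- rev(cumsum(rev(g)))            # sum of g_i over i >= k
  s1 <- rev(cumsum(rev(g * x_sorted))) # sum of g_i x_i over i >= k
  # first index with x_i >= t:  (number of x_i < t) + 1
  k <- findInterval(candidates, x_sorted, left.open = TRUE) + 1L
  h <- numeric(length(candidates))
  inside <- k <= n
  h[inside] <- s1[k[inside]] - candidates[inside] * s0[k[inside]]
  h
}

# Candidate knot locations for one (sorted or unsorted) feature column.
candidate_knots <- function(x) sort(unique(c(0, x)))

#' Exact linear minimization oracle for one coordinate
#'
#' Finds the best two-point signed measure `s* = (tau/2) delta_{t+} -
#' (tau/2) delta_{t-}` for the linearized objective: `t+` minimizes the
#' hinge correlation `h(t) = <g, psi(t)>` and `t-` maximizes it
#' (equivalently minimizes `-h`), both over the candidate set
#' `{0} U {x_i}` on which the piecewise-linear `h` attains its extrema.
#' Ties are broken toward the smallest `t`.  When `min h >= max h`
#' (both are then 0) the zero measure is a conditional gradient and the
#' current measure is optimal on this coordinate.
#'
#' @param g n-vector loss gradient at current predictions.
#' @param x_d n-vector scaled feature column.
#' @param tau positive total-variation budget.
#' @param coord coordinate index recorded in the result.
#' @return object of class `lmo_result`: list with `coord`, `t_plus`,
#'   `t_minus`, `h_plus`, `h_minus`, `o_star` (linearized objective of
#'   `s*`, `<= 0`), and `optimal_flag`.
#' @export
lmo_coordinate <- function(g, x_d, tau, coord = 1L) {
  if (length(x_d) == 0L) stop("empty feature vector")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0) stop("tau must be > 0")
  ord <- order(x_d)
  xs <- x_d[ord]
  cand <- candidate_knots(xs)
  h <- hinge_score_profile(g[ord], xs, cand)
  ip <- which.min(h)   # first (= smallest t) minimizer
  im <- which.max(h)
  h_plus <- h[ip]; h_minus <- h[im]
  flag <- (h_plus - h_minus) >= 0
  structure(list(coord = as.integer(coord),
                 t_plus = cand[ip], t_minus = cand[im],
                 h_plus = h_plus, h_minus = h_minus,
                 o_star = if (flag) 0 else (tau / 2) * (h_plus - h_minus),
                 optimal_flag = flag),
            class = "lmo_result")
}

#' Linear minimization oracle for the additive-model measure ball
#'
#' Runs [lmo_coordinate()] on every feature column and returns the
#' coordinate with the smallest linearized objective `o*` (ties broken
#' toward the smallest coordinate index).  The current measure is
#' optimal iff every coordinate's zero measure is a conditional
#' gradient.
#'
#' @param g n-vector loss gradient.
#' @param X n x D matrix of scaled features.
#' @param tau positive total-variation budget.
#' @return an `lmo_result` (see [lmo_coordinate()]).
#' @export
lmo_gam <- function(g, X, tau) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (D == 0L) stop("design has no columns")
  best <- NULL
  all_flag <- TRUE
  for (d in seq_len(D)) {
    r <- lmo_coordinate(g, X[, d], tau, coord = d)
    all_flag <- all_flag && r$optimal_flag
    if (is.null(best) || r$o_star < best$o_star) best <- r
  }
  best$optimal_flag <- all_flag
  if (all_flag) best$o_star <- 0
  best
}

#' Duality gap of the measure block
#'
#' `gap = <g, E_x mu> - <g, E_x s*>`, the difference between the
#' linearized objective at the current measure and at the conditional
#' gradient.  By convexity this bounds the suboptimality of the current
#' measure (at a stationary intercept, of the joint problem).  When the
#' LMO flags optimality the conditional gradient is the zero measure and
#' the second term is 0.
#'
#' @param g n-vector loss gradient at current predictions.
#' @param preds_mu n-vector `E_x mu`, the measure part of the current
#'   predictions (intercept excluded).
#' @param lmo an `lmo_result`.
#' @param preds_sstar optional n-vector of predictions of the two-point
#'   conditional gradient; when omitted its exact linearized objective
#'   `o_star` from the LMO is used (they coincide by construction).
#' @return nonnegative gap.
#' @export
duality_gap <- function(g, preds_mu, lmo, preds_sstar = NULL) {
  stopifnot(inherits(lmo, "lmo_result"))
  o <- if (lmo$optimal_flag) 0
       else if (!is.null(preds_sstar)) sum(g * preds_sstar)
       else lmo$o_star
  sum(g * preds_mu) - o
}
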