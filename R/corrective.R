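#' Restricted finite-dimensional problem at fixed knots
#'
#' The fully-corrective step re-optimizes all knot weights, at fixed knot
#' locations, under the l1 budget and the per-coordinate zero-net-mass
#' constraints.  This bundles the hinge basis matrix and the grouping of
#' knots by coordinate.
#'
#' @param knots data.frame with columns `coord`, `t` (one row per knot).
#' @param X_scaled n x D matrix of scaled features.
#' @param tau nonnegative total-variation budget.
#' @return object of class `restricted_problem` with `knots`, `basis`
#'   (n x K), `tau`, `groups` (coordinate of each column).
#' @export
restricted_problem <- function(knots, X_scaled, tau) {
  X <- as.matrix(X_scaled)
  knots <- as.data.frame(knots)
  stopifnot(all(c("coord", "t") %in% names(knots)))
  if (length(tau) != 1L || !is.finite(tau) || tau < 0) stop("tau must be >= 0")
  K <- nrow(knots)
  B <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) B[, k] <- eval_basis(knots$t[k], knots$coord[k], X)
  structure(list(knots = knots, basis = B, tau = tau,
                 groups = as.integer(knots$coord)),
            class = "restricted_problem")
}

#' Vertex oracle of the constraint polytope
#'
#' The feasible set `{w : per-group sums 0, ||w||_1 <= tau}` is the
#' convex hull of the origin and the paired vertices
#' `(tau/2)(e_i - e_j)` with `i, j` in the same group.  This returns the
#' vertex minimizing `<grad_w, v>`: within each group `i = argmin grad`,
#' `j = argmax grad`; the best group wins; the zero vertex is also a
#' candidate so the inner Frank-Wolfe gap is valid.  Ties go to the
#' smallest indices.
#'
#' @param grad_w K-vector gradient with respect to the weights.
#' @param tau positive budget.
#' @param groups integer K-vector of group (coordinate) labels.
#' @return list with `i`, `j` (0 when the zero vertex wins), `value`
#'   (`<grad_w, v>`, always `<= 0`) and `zero` flag.
#' @export
inner_vertex_lmo <- function(grad_w, tau, groups) {
  best_i <- 0L; best_j <- 0L; best_val <- 0
  for (grp in sort(unique(groups))) {
    idx <- which(groups == grp)
    if (length(idx) < 2L) next
    gi <- grad_w[idx]
    i <- idx[which.min(gi)]
    j <- idx[which.max(gi)]
    val <- (tau / 2) * (grad_w[i] - grad_w[j])
    if (val < best_val) { best_val <- val; best_i <- i; best_j <- j }
  }
  list(i = best_i, j = best_j, value = best_val, zero = (best_i == 0L))
}

#' Exact/bisection line search along a feasible direction
#'
#' Minimizes `gamma -> L(preds + gamma * direction_preds)` over
#' `[0, gamma_max]`.  Squared loss: closed-form minimizer of the 1-D
#' quadratic, clipped.  Other losses: bisection on the (monotone)
#' derivative to `|phi'| <= 1e-10` or 100 iterations.  The returned step
#' never increases the objective.
#'
#' @param loss a [loss_spec()].
#' @param y n-vector responses.
#' @param preds current predictions.
#' @param direction_preds prediction change of a unit step.
#' @param gamma_max upper bound of the step (default 1).
#' @return step length in `[0, gamma_max]`.
#' @export
line_search <- function(loss, y, preds, direction_preds, gamma_max = 1) {
  d2 <- sum(direction_preds^2)
  if (d2 == 0 || gamma_max <= 0) return(0)
  g0 <- sum(loss_value_grad(loss, preds, y)$grad * direction_preds)
  if (g0 >= 0) return(0)
  if (loss$kind == "squared") {
    return(min(gamma_max, -g0 / d2))
  }
  dphi <- function(gam) {
    sum(loss_value_grad(loss, preds + gam * direction_preds, y)$grad *
          direction_preds)
  }
  hi <- gamma_max
  fhi <- dphi(hi)
  if (fhi <= 0) return(gamma_max)
  lo <- 0; flo <- g0
  gam <- hi
  for (it in seq_len(100L)) {
    gam <- (lo + hi) / 2
    f <- dphi(gam)
    if (abs(f) <= 1e-10) break
    if (f > 0) hi <- gam else lo <- gam
  }
  gam
}

# Equality-constrained polish step on the current active face.  Fixing
# the sign pattern of the nonzero weights, the face is an affine set
# (group sums zero; signed sum fixed when the l1 budget is tight).  A
# majorized Newton direction is computed from the curvature *bound* of
# the loss (exact Newton for squared loss; no pointwise second
# derivatives are needed), restricted to the face, and followed by an
# exact line search capped before any sign change.  Purely an
# accelerator: never increases the objective, and the pairwise
# Frank-Wolfe gap remains the certificate.  Returns NULL or
# list(w, z, gamma).
face_polish <- function(B, w, z, y, loss, tau, groups) {
  act <- which(w != 0)
  if (length(act) < 2L) return(NULL)
  sg <- sign(w[act])
  l1 <- sum(abs(w))
  l1_tight <- l1 >= tau * (1 - 1e-10)
  Ba <- B[, act, drop = FALSE]
  g <- loss_value_grad(loss, z, y)$grad
  grad <- drop(crossprod(Ba, g))
  H <- loss_curvature_bound(loss) * crossprod(Ba)
  grps <- groups[act]
  C <- t(vapply(unique(grps), function(grp) as.numeric(grps == grp),
                numeric(length(act))))
  if (l1_tight) C <- rbind(C, sg)
  ka <- length(act); kc <- nrow(C)
  ridge <- 1e-11 * max(diag(H), 1e-300)
  KKT <- rbind(cbind(H + diag(ridge, ka), t(C)),
               cbind(C, matrix(0, kc, kc)))
  sol <- tryCatch(solve(KKT, c(-grad, rep(0, kc))),
                  error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  d <- sol[seq_len(ka)]
  if (all(abs(d) < 1e-15)) return(NULL)
  gamma_max <- 1
  crossing <- which(d * sg < 0)
  if (length(crossing)) {
    gamma_max <- min(gamma_max, -w[act][crossing] / d[crossing])
  }
  if (!l1_tight) {
    growth <- sum(sg * d)
    if (growth > 0) gamma_max <- min(gamma_max, (tau - l1) / growth)
  }
  if (gamma_max <= 0) return(NULL)
  dz <- drop(Ba %*% d)
  gamma <- line_search(loss, y, z, dz, gamma_max)
  if (gamma <= 0) return(NULL)
  w2 <- w
  w2[act] <- w2[act] + gamma * d
  # snap exact zeros at the cap so support identification is clean
  w2[act][abs(w2[act]) < 1e-14 * max(abs(w2[act]), 1)] <- 0
  list(w = w2, z = z + gamma * dz, gamma = gamma)
}

# Decompose a feasible weight vector into paired vertices by greedy
# transport matching of positive against negative mass within each group.
# Returns parallel vectors (i, j, a) with w ~= sum_k a_k (tau/2)(e_i - e_j).
decompose_pairs <- function(w, groups, tau) {
  is <- integer(0); js <- integer(0); as <- numeric(0)
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    pos <- idx[w[idx] > 0]
    neg <- idx[w[idx] < 0]
    pw <- w[pos]; nw <- -w[neg]
    pi <- 1L; ni <- 1L
    while (pi <= length(pos) && ni <= length(neg)) {
      m <- min(pw[pi], nw[ni])
      if (m > 0) {
        is <- c(is, pos[pi]); js <- c(js, neg[ni]); as <- c(as, m / (tau / 2))
      }
      pw[pi] <- pw[pi] - m
      nw[ni] <- nw[ni] - m
      if (pw[pi] <= 0) pi <- pi + 1L
      if (nw[ni] <= 0) ni <- ni + 1L
    }
  }
  list(i = is, j = js, a = as)
}

#' Fully-corrective step: solve the restricted convex problem
#'
#' Minimizes `L(B w + c) ` over weights `w` in the polytope
#' `{per-group sums 0, ||w||_1 <= tau}` jointly with the unpenalized
#' intercept `c`, by pairwise-vertex Frank-Wolfe with exact line search.
#' Moves are differences of polytope vertices from a maintained vertex
#' decomposition, so per-group sum-zero feasibility holds exactly by
#' construction at every iterate.  The intercept is re-minimized exactly
#' after every step, which keeps the outer duality-gap certificate valid
#' for the joint problem.
#'
#' @param problem a [restricted_problem()].
#' @param y n-vector responses.
#' @param loss a [loss_spec()].
#' @param w0 feasible warm-start weights (default 0).  A materially
#'   infeasible warm start is projected to feasibility (group recentring
#'   and l1 rescaling) with a warning.
#' @param c0 warm-start intercept (default 0).
#' @param tol_inner relative Frank-Wolfe gap tolerance.
#' @param max_inner iteration cap (a warning is issued on hitting it).
#' @param z0 optional precomputed predictions `B w0 + c0` (used by the
#'   outer loop to keep objective traces bitwise monotone).
#' @return list with `w`, `c`, `obj`, `inner_gap`, `z` (fitted
#'   predictions) and `iterations`.
#' @export
restricted_solve <- function(problem, y, loss, w0 = NULL, c0 = NULL,
                             tol_inner = 1e-8, max_inner = 10000L,
                             z0 = NULL) {
  stopifnot(inherits(problem, "restricted_problem"))
  B <- problem$basis; tau <- problem$tau; groups <- problem$groups
  K <- ncol(B); n <- nrow(B)
  if (length(y) != n) stop("y length must match the basis rows")
  if (is.null(w0)) w0 <- numeric(K)
  if (is.null(c0)) c0 <- 0
  if (length(w0) != K) stop("warm start has wrong length")

  w <- w0
  w_touched <- FALSE
  if (K > 0L && tau > 0) {
    # restore exact feasibility of the warm start
    gs <- tapply(w, groups, sum)
    l1 <- sum(abs(w))
    viol <- max(abs(gs), l1 - tau)
    if (viol > 1e-9 * max(1, tau)) {
      warning("infeasible warm start projected to feasibility")
      w_touched <- TRUE
      for (grp in unique(groups)) {
        idx <- which(groups == grp)
        w[idx] <- w[idx] - mean(w[idx])
      }
      l1 <- sum(abs(w))
      if (l1 > tau) w <- w * (tau / l1)
    } else if (viol > 1e-12 * max(1, tau)) {
      # exactify: absorb roundoff imbalance into the largest-|w| member
      for (grp in unique(groups)) {
        idx <- which(groups == grp)
        s <- sum(w[idx])
        if (s != 0) {
          k <- idx[which.max(abs(w[idx]))]
          w[k] <- w[k] - s
          w_touched <- TRUE
        }
      }
      l1 <- sum(abs(w))
      if (l1 > tau) { w <- w * (tau / l1); w_touched <- TRUE }
    }
    # imbalance at roundoff level is tolerated here; the outer loop
    # restores exact balance through zero-column slack knots
  } else {
    w_touched <- !all(w0 == 0)
    w <- numeric(K)
  }

  z <- if (!is.null(z0) && !w_touched) z0
       else if (K > 0L) drop(B %*% w) + c0
       else rep(c0, n)
  cc <- c0

  # warm-start snapshot: the return value is never worse than this, so
  # outer objective traces are exactly monotone despite 1-ulp jitter in
  # the closed-form line searches and intercept shifts
  w_in <- w; c_in <- cc; z_in <- z
  obj_in <- dataset_loss_grad(loss, z, y)$value

  dc <- solve_intercept_shift(loss, z, y)
  z <- z + dc; cc <- cc + dc

  if (K == 0L || tau == 0) {
    lg <- dataset_loss_grad(loss, z, y)
    if (lg$value > obj_in) {
      return(list(w = w_in, c = c_in, obj = obj_in, inner_gap = 0, z = z_in,
                  iterations = 0L))
    }
    return(list(w = w, c = cc, obj = lg$value, inner_gap = 0, z = z,
                iterations = 0L))
  }

  dec <- decompose_pairs(w, groups, tau)
  av_i <- dec$i; av_j <- dec$j; av_a <- dec$a

  half <- tau / 2
  obj <- NA_real_; gap <- Inf
  it <- 0L
  last_polished <- integer(0)
  while (it < max_inner) {
    it <- it + 1L
    lg <- dataset_loss_grad(loss, z, y)
    obj <- lg$value
    grad_w <- drop(crossprod(B, lg$grad))
    s <- inner_vertex_lmo(grad_w, tau, groups)
    gap <- sum(grad_w * w) - s$value
    if (gap <= tol_inner * max(1, abs(obj))) break

    # away vertex: worst active vertex, or the origin when slack remains
    slack <- max(0, 1 - sum(av_a))
    a_idx <- 0L; a_val <- if (slack > 1e-15) 0 else -Inf
    if (length(av_a)) {
      vals <- half * (grad_w[av_i] - grad_w[av_j])
      k <- which.max(vals)
      if (vals[k] > a_val) { a_idx <- k; a_val <- vals[k] }
    }
    if (!is.finite(a_val)) break  # no movable mass

    dz <- numeric(n)
    if (!s$zero) dz <- dz + half * (B[, s$i] - B[, s$j])
    if (a_idx > 0L) dz <- dz - half * (B[, av_i[a_idx]] - B[, av_j[a_idx]])
    gamma_max <- if (a_idx > 0L) av_a[a_idx] else slack
    if (s$zero && a_idx == 0L) break
    gamma <- line_search(loss, y, z, dz, gamma_max)
    if (gamma <= 0) break

    z <- z + gamma * dz
    if (!s$zero) {
      w[s$i] <- w[s$i] + gamma * half
      w[s$j] <- w[s$j] - gamma * half
      m <- which(av_i == s$i & av_j == s$j)
      if (length(m)) {
        av_a[m[1]] <- av_a[m[1]] + gamma
      } else {
        av_i <- c(av_i, s$i); av_j <- c(av_j, s$j); av_a <- c(av_a, gamma)
      }
    }
    if (a_idx > 0L) {
      w[av_i[a_idx]] <- w[av_i[a_idx]] - gamma * half
      w[av_j[a_idx]] <- w[av_j[a_idx]] + gamma * half
      av_a[a_idx] <- av_a[a_idx] - gamma
      if (av_a[a_idx] <= 1e-15) {
        keep <- seq_along(av_a) != a_idx
        av_i <- av_i[keep]; av_j <- av_j[keep]; av_a <- av_a[keep]
      }
    }
    dc <- solve_intercept_shift(loss, z, y)
    z <- z + dc; cc <- cc + dc

    # accelerator: majorized Newton steps on the active face, run when
    # the support has changed (or periodically as a safety net)
    support <- which(w != 0)
    if (!identical(support, last_polished) || it %% 20L == 0L) {
      polished <- FALSE
      obj_cur <- dataset_loss_grad(loss, z, y)$value
      for (ps in seq_len(8L)) {
        fp <- face_polish(B, w, z, y, loss, tau, groups)
        if (is.null(fp)) break
        w <- fp$w; z <- fp$z
        dc <- solve_intercept_shift(loss, z, y)
        z <- z + dc; cc <- cc + dc
        polished <- TRUE
        obj_new <- dataset_loss_grad(loss, z, y)$value
        done <- obj_cur - obj_new <= 0.01 * tol_inner * max(1, abs(obj_new))
        obj_cur <- obj_new
        if (done) break
      }
      last_polished <- which(w != 0)
      if (polished) {
        dec <- decompose_pairs(w, groups, tau)
        av_i <- dec$i; av_j <- dec$j; av_a <- dec$a
      }
    }
  }
  if (it >= max_inner && gap > tol_inner * max(1, abs(obj))) {
    warning(sprintf("inner solver hit max_inner=%d with gap %g", max_inner, gap))
  }
  lg <- dataset_loss_grad(loss, z, y)
  if (lg$value > obj_in) {
    return(list(w = w_in, c = c_in, obj = obj_in, inner_gap = gap, z = z_in,
                iterations = it))
  }
  list(w = w, c = cc, obj = lg$value, inner_gap = gap, z = z, iterations = it)
}
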