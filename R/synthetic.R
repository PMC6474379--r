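#' Specification of a synthetic saturating-spline dataset
#'
#' Describes a ground truth that is itself a feasible saturating-spline
#' additive model: a chosen subset of coordinates is active, each with a
#' known set of interior knots whose weights sum to zero exactly, so the
#' truth saturates and its TV is known.  Features are uniform on
#' `[0,1]^D`; responses are the truth plus Gaussian noise, optionally
#' with a heavy-tailed outlier contamination on a seeded subset, or
#' `{-1,+1}` labels drawn with logistic probabilities.
#'
#' @param n number of observations.
#' @param D number of features.
#' @param active_coords integer subset of `1..D` carrying signal.
#' @param knots_per_active knots per active coordinate (>= 2, so the
#'   zero-net-mass constraint can hold).
#' @param noise_kind `"gaussian"` or `"outlier_mix"`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param outlier_frac fraction of rows contaminated (outlier_mix only);
#'   exactly `round(outlier_frac * n)` rows are hit.
#' @param outlier_scale multiple of `noise_sd` for the contamination.
#' @param label_kind `"real"` or `"logistic"`.
#' @param tv_per_coord total variation of each active coordinate function
#'   (default 4: an order-one signal against the default noise).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 200L, D = 1L, active_coords = 1L,
                           knots_per_active = 3L,
                           noise_kind = c("gaussian", "outlier_mix"),
                           noise_sd = 0.1, outlier_frac = 0.1,
                           outlier_scale = 10, label_kind = c("real", "logistic"),
                           tv_per_coord = 4, seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  label_kind <- match.arg(label_kind)
  active_coords <- as.integer(active_coords)
  if (length(active_coords) && (any(active_coords < 1L) ||
                                any(active_coords > D))) {
    stop("active_coords must lie in 1..D")
  }
  if (length(active_coords) == 0L && knots_per_active > 0L) {
    stop("empty active set with nonzero knots_per_active")
  }
  if (length(active_coords) && knots_per_active < 2L) {
    stop("knots_per_active must be >= 2 (weights must sum to zero)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n = as.integer(n), D = as.integer(D),
                 active_coords = active_coords,
                 knots_per_active = as.integer(knots_per_active),
                 noise_kind = noise_kind, noise_sd = noise_sd,
                 outlier_frac = outlier_frac, outlier_scale = outlier_scale,
                 label_kind = label_kind, tv_per_coord = tv_per_coord,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a dataset with known saturating ground truth
#'
#' Uses R's Mersenne-Twister generator with inversion normals, seeded
#' from `spec$seed`; identical specs produce identical bytes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `X` (n x D raw features in `[0,1]`), `y`
#'   (responses or `{-1,+1}` labels) and `truth` (a feasible
#'   [spline_model()] with identity scaling).
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  X <- matrix(stats::runif(spec$n * spec$D), spec$n, spec$D)
  atoms <- empty_atoms()
  for (d in spec$active_coords) {
    K <- spec$knots_per_active
    t <- sort(stats::runif(K, 0.05, 0.95))
    repeat {
      w <- stats::rnorm(K)
      w <- w - mean(w)
      if (sum(abs(w)) > 1e-8) break
    }
    w <- w * spec$tv_per_coord / sum(abs(w))
    w <- w - mean(w)  # exact zero net mass after rescaling roundoff
    atoms <- rbind(atoms, data.frame(coord = d, t = t, w = w))
  }
  truth <- spline_model(atomic_measure(atoms, D = spec$D), intercept = 0,
                        scaling = data.frame(shift = rep(0, spec$D),
                                             range = rep(1, spec$D)),
                        tau = sum(abs(atoms$w)))
  f <- eval_spline(truth, X)
  if (spec$label_kind == "logistic") {
    y <- ifelse(stats::runif(spec$n) < stats::plogis(f), 1, -1)
  } else {
    y <- f + spec$noise_sd * stats::rnorm(spec$n)
    if (spec$noise_kind == "outlier_mix") {
      n_out <- round(spec$outlier_frac * spec$n)
      idx <- sample(spec$n, n_out)
      y[idx] <- y[idx] + spec$outlier_scale * spec$noise_sd * stats::rnorm(n_out)
    }
  }
  list(X = X, y = y, truth = truth)
}

#' Gridded brute-force reference solver (test oracle)
#'
#' Solves the same fitting objective with the *full* candidate knot set
#' `{0} U {x_i}` on every coordinate, under the l1 budget and
#' per-coordinate zero-net-mass constraints, using an algorithm
#' independent of the main pairwise Frank-Wolfe path: the polytope is
#' parametrized by the simplex of its paired vertices
#' `(tau/2)(e_i - e_j)` and the problem is solved by accelerated
#' proximal gradient (FISTA with adaptive restart) with projection onto
#' the simplex, plus exact intercept minimization.  Intended for tiny
#' instances only; refuses `n > max_n`.
#'
#' @param X raw feature matrix (n x D).
#' @param y responses.
#' @param loss a [loss_spec()].
#' @param tau nonnegative budget.
#' @param tol relative suboptimality certificate target.
#' @param max_n refusal threshold (default 50).
#' @return list with `obj`, `w`, `c`, `knots` (data.frame coord, t),
#'   `gap` (simplex Frank-Wolfe certificate of the returned point).
#' @export
gridded_oracle <- function(X, y, loss = loss_spec("squared"), tau,
                           tol = 1e-9, max_n = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > max_n) {
    stop(sprintf("gridded_oracle refuses n=%d > max_n=%d (test oracle only)",
                 n, max_n))
  }
  if (length(tau) != 1L || !is.finite(tau) || tau < 0) stop("tau must be >= 0")
  sd_ <- scale_fit_transform(X)
  Xs <- sd_$X_scaled
  knots <- do.call(rbind, lapply(seq_len(ncol(Xs)), function(d) {
    data.frame(coord = d, t = candidate_knots(Xs[, d]))
  }))
  if (tau == 0) {
    dc <- solve_intercept_shift(loss, rep(0, n), y)
    obj <- dataset_loss_grad(loss, rep(dc, n), y)$value
    return(list(obj = obj, w = numeric(nrow(knots)), c = dc, knots = knots,
                gap = 0))
  }
  B <- matrix(0, n, nrow(knots))
  for (k in seq_len(nrow(knots))) {
    B[, k] <- pmax(Xs[, knots$coord[k]] - knots$t[k], 0)
  }
  res <- fista_pair_simplex(B, as.integer(knots$coord), y, loss, tau, tol)
  list(obj = res$obj, w = res$w, c = res$c, knots = knots, gap = res$gap)
}

# Project v onto {a >= 0, sum(a) <= 1}.
project_simplex_ineq <- function(v) {
  v <- pmax(v, 0)
  s <- sum(v)
  if (s <= 1) return(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# FISTA over the pair-vertex simplex: w = M a with columns of M equal to
# (tau/2)(B[,i] - B[,j]) for same-group ordered pairs, a in the unit
# simplex (inequality form).  Exact intercept interleaved; certificate is
# the simplex linear-minimization gap at a stationary intercept.
fista_pair_simplex <- function(B, groups, y, loss, tau, tol,
                               max_iter = 200000L) {
  n <- nrow(B); K <- ncol(B)
  pi_ <- integer(0); pj_ <- integer(0)
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    if (length(idx) < 2L) next
    pr <- expand.grid(i = idx, j = idx)
    pr <- pr[pr$i != pr$j, ]
    pi_ <- c(pi_, pr$i); pj_ <- c(pj_, pr$j)
  }
  P <- length(pi_)
  if (P == 0L) {
    dc <- solve_intercept_shift(loss, rep(0, n), y)
    obj <- dataset_loss_grad(loss, rep(dc, n), y)$value
    return(list(obj = obj, w = numeric(K), c = dc, gap = 0))
  }
  M <- (tau / 2) * (B[, pi_, drop = FALSE] - B[, pj_, drop = FALSE])
  # Lipschitz bound: curvature * ||M||_2^2 via power iteration
  v <- stats::rnorm(P); v <- v / sqrt(sum(v^2))
  for (i in 1:30) {
    u <- drop(M %*% v); v <- drop(crossprod(M, u))
    nv <- sqrt(sum(v^2)); if (nv == 0) break
    v <- v / nv
  }
  Lip <- loss_curvature_bound(loss) * max(nv, 1e-12) * 1.05
  step <- 1 / Lip

  a <- numeric(P); a_prev <- a
  tt <- 1
  cc <- solve_intercept_shift(loss, rep(0, n), y)
  obj_at <- function(a, cc) {
    dataset_loss_grad(loss, drop(M %*% a) + cc, y)$value
  }
  obj_prev <- obj_at(a, cc)
  gap <- Inf; obj <- obj_prev
  for (it in seq_len(max_iter)) {
    mom <- a + ((tt - 1) / (tt + 2)) * (a - a_prev)
    z <- drop(M %*% mom) + cc
    g <- loss_value_grad(loss, z, y)$grad
    grad_a <- drop(crossprod(M, g))
    a_new <- project_simplex_ineq(mom - step * grad_a)
    a_prev <- a
    a <- a_new
    tt <- tt + 1
    if (it %% 10L == 0L || it == 1L) {
      dc <- solve_intercept_shift(loss, drop(M %*% a) + cc, y)
      cc <- cc + dc
      obj <- obj_at(a, cc)
      if (obj > obj_prev) { tt <- 1; a_prev <- a }  # adaptive restart
      obj_prev <- obj
      z <- drop(M %*% a) + cc
      g <- loss_value_grad(loss, z, y)$grad
      grad_a <- drop(crossprod(M, g))
      gap <- sum(grad_a * a) - min(0, min(grad_a))
      if (gap <= tol * max(1, abs(obj))) break
    }
  }
  # map back to knot weights
  w <- numeric(K)
  nz <- which(a > 0)
  for (k in nz) {
    w[pi_[k]] <- w[pi_[k]] + a[k] * tau / 2
    w[pj_[k]] <- w[pj_[k]] - a[k] * tau / 2
  }
  list(obj = obj, w = w, c = cc, gap = gap)
}
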