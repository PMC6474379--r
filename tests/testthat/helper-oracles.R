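# Independent low-tech oracles used to check the exact routines.

# Dense evaluation of h(t) = sum_i g_i (x_i - t)_+ by direct summation
# (chunked so the n x G matrix stays small).  Deliberately does not share
# the suffix-sum code path of hinge_score_profile.
grid_hinge <- function(g, x, ts, chunk = 20000L) {
  out <- numeric(length(ts))
  for (s in seq(1, length(ts), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(ts))
    out[idx] <- as.vector(g %*% pmax(outer(x, ts[idx], "-"), 0))
  }
  out
}

# A random feasible atomic measure: balanced weights on every active
# coordinate, knots at interior points.
random_measure <- function(D = 2L, k_per = 3L, tv = 2) {
  atoms <- data.frame(coord = integer(0), t = numeric(0), w = numeric(0))
  for (d in seq_len(D)) {
    t <- sort(runif(k_per, 0.05, 0.95))
    w <- rnorm(k_per); w <- w - mean(w)
    if (sum(abs(w)) < 1e-12) w <- c(1, -1, rep(0, k_per - 2L))
    w <- w * tv / sum(abs(w)); w <- w - mean(w)
    atoms <- rbind(atoms, data.frame(coord = d, t = t, w = w))
  }
  atomic_measure(atoms, D = D)
}

# Raw value whose scaled image is s, per coordinate.
raw_at <- function(model, s, d) {
  model$scaling$shift[d] + s * model$scaling$range[d]
}

# Evaluate a model at a raw point where coordinate d is at scaled value s
# and all other coordinates sit at scaled 0 (their contribution is then
# constant across s, so differences isolate coordinate d).
eval_at_scaled <- function(model, s, d) {
  D <- model$measure$D
  x <- vapply(seq_len(D), function(j) raw_at(model, 0, j), 0)
  x[d] <- raw_at(model, s, d)
  eval_spline(model, matrix(x, nrow = 1))
}

expect_feasible_model <- function(model, tau, tol_rel = 1e-9) {
  tv <- tv_norm(model$measure)
  expect_lte(tv, tau * (1 + tol_rel))
  for (d in seq_len(model$measure$D)) {
    expect_lte(abs(net_mass(model$measure, d)), 1e-9 * max(1, tv))
  }
}
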