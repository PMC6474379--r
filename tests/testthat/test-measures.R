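test_that("eval_basis matches the hinge definition and its edge cases", {
  X <- matrix(c(0.2, 0.8), ncol = 1)
  expect_equal(eval_basis(0, 1, X), c(0.2, 0.8))
  expect_equal(eval_basis(1, 1, X), c(0, 0))
  expect_equal(eval_basis(0.5, 1, matrix(c(0.25, 0.75), ncol = 1)), c(0, 0.25))
  expect_error(eval_basis(0.5, 3, X), "coord")
  # nonnegative and componentwise nonincreasing in t
  set.seed(1)
  Xr <- matrix(runif(20), ncol = 1)
  prev <- eval_basis(0, 1, Xr)
  for (t in seq(0.1, 1, by = 0.1)) {
    cur <- eval_basis(t, 1, Xr)
    expect_true(all(cur >= 0) && all(cur <= prev))
    prev <- cur
  }
})

test_that("eval_spline evaluates hinge combinations and saturates", {
  mu <- atomic_measure(data.frame(coord = 1, t = c(0.25, 0.75), w = c(1, -1)))
  m <- spline_model(mu, intercept = 0)
  expect_equal(eval_spline(m, matrix(0.5)), 0.25)
  # saturation: values beyond [0,1] equal the boundary values
  v <- eval_spline(m, matrix(c(-3, 0, 1, 5), ncol = 1))
  expect_identical(v[1], v[2])
  expect_identical(v[3], v[4])
  expect_equal(v[4], 0.5)
  # constant model
  m0 <- spline_model(atomic_measure(D = 1), intercept = 1.7)
  expect_equal(eval_spline(m0, matrix(c(-10, 0.3, 42), ncol = 1)),
               rep(1.7, 3))
})

test_that("saturation holds for random feasible models, far out, all coords", {
  set.seed(7)
  for (rep in 1:5) {
    mu <- random_measure(D = 3, k_per = 4, tv = runif(1, 0.5, 5))
    m <- spline_model(mu, intercept = rnorm(1),
                      scaling = data.frame(shift = rnorm(3), range = runif(3, 0.5, 3)))
    for (d in 1:3) {
      lo0 <- eval_at_scaled(m, 0, d); lo <- eval_at_scaled(m, -10, d)
      hi1 <- eval_at_scaled(m, 1, d); hi <- eval_at_scaled(m, 10, d)
      expect_lte(abs(lo - lo0), 1e-12 * max(1, abs(lo0)))
      expect_lte(abs(hi - hi1), 1e-12 * max(1, abs(hi1)))
    }
  }
})

test_that("tv_norm is the l1 norm of the weights", {
  expect_equal(tv_norm(atomic_measure(
    data.frame(coord = 1, t = c(0.25, 0.75), w = c(1, -1)))), 2)
  expect_equal(tv_norm(atomic_measure(D = 2)), 0)
  tau <- 3
  expect_equal(tv_norm(atomic_measure(
    data.frame(coord = 1, t = c(0.5, 0.9), w = c(tau / 2, -tau / 2)))), tau)
})

test_that("tv_norm equals the finite-difference TV of the spline derivative", {
  set.seed(11)
  for (rep in 1:5) {
    mu <- random_measure(D = 1, k_per = 5, tv = runif(1, 0.5, 4))
    m <- spline_model(mu, intercept = rnorm(1))
    br <- sort(unique(c(-0.5, mu$atoms$t, 1.5)))
    # two probe points inside each inter-knot segment give exact slopes
    slopes <- vapply(seq_len(length(br) - 1L), function(k) {
      a <- br[k] + 0.25 * (br[k + 1] - br[k])
      b <- br[k] + 0.75 * (br[k + 1] - br[k])
      (eval_spline(m, matrix(b)) - eval_spline(m, matrix(a))) / (b - a)
    }, 0)
    tv_fd <- sum(abs(diff(c(0, slopes, 0))))
    expect_lte(abs(tv_fd - tv_norm(mu)), 1e-8)
  }
})

test_that("net_mass sums weights per coordinate", {
  mu <- atomic_measure(data.frame(coord = c(1, 1, 2), t = c(0.25, 0.75, 0.5),
                                  w = c(1, -1, 0.3)), D = 2)
  expect_equal(net_mass(mu, 1), 0)
  expect_equal(net_mass(mu, 2), 0.3)
  mu2 <- atomic_measure(data.frame(coord = 2, t = 0.5, w = 1), D = 2)
  expect_equal(net_mass(mu2, 1), 0)
  expect_error(net_mass(mu, 3), "coord")
})

test_that("prune_merge merges duplicates, drops tiny atoms, and is idempotent", {
  m1 <- atomic_measure(data.frame(coord = 1, t = c(0.5, 0.5), w = c(1, -1)))
  expect_equal(nrow(m1$atoms), 0L)
  m2 <- prune_merge(atomic_measure(
    data.frame(coord = 1, t = c(0.5, 0.7), w = c(1e-12, 1))), w_tol = 1e-9)
  expect_equal(m2$atoms$t, 0.7)
  expect_equal(m2$atoms$w, 1)
  # idempotence, and bounded net-mass drift per coordinate
  set.seed(3)
  for (rep in 1:10) {
    mu <- random_measure(D = 2, k_per = 4, tv = 2)
    w_tol <- 10^runif(1, -10, -2)
    p1 <- prune_merge(mu, w_tol)
    expect_identical(prune_merge(p1, w_tol)$atoms, p1$atoms)
    n_pruned <- nrow(mu$atoms) - nrow(p1$atoms)
    for (d in 1:2) {
      expect_lte(abs(net_mass(p1, d) - net_mass(mu, d)),
                 n_pruned * w_tol + 1e-15)
    }
  }
})

test_that("measure constructor validates invariants", {
  expect_error(atomic_measure(data.frame(coord = 1, t = 1.5, w = 1)), "0,1")
  expect_error(atomic_measure(data.frame(coord = 3, t = 0.5, w = 1), D = 2),
               "coord")
  expect_error(atomic_measure(data.frame(coord = 1, t = 0.5, w = Inf)),
               "finite")
})
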