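test_that("hinge_score_profile matches direct summation at the candidates", {
  # frozen examples (verified against grid_hinge below)
  h <- hinge_score_profile(c(1, -1), c(0.2, 0.8))
  expect_equal(h, c(-0.6, -0.6, 0))   # at candidates 0, 0.2, 0.8
  expect_equal(hinge_score_profile(c(0, 0), c(0.2, 0.8)), c(0, 0, 0))
  expect_equal(hinge_score_profile(1, 0.5), c(0.5, 0))
  expect_error(hinge_score_profile(c(1, 1), c(0.8, 0.2)), "sorted")
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    x <- sort(runif(n))
    x[sample(n, 2)] <- x[1]  # exercise repeated values
    x <- sort(x)
    g <- rnorm(n)
    cand <- sort(unique(c(0, x)))
    expect_equal(hinge_score_profile(g, x, cand), grid_hinge(g, x, cand),
                 tolerance = 1e-12)
  }
})

test_that("lmo_coordinate is exact against dense gridding", {
  # frozen two-point example
  r <- lmo_coordinate(c(1, -1), c(0.2, 0.8), tau = 2)
  expect_equal(r$t_plus, 0)
  expect_equal(r$t_minus, 0.8)
  expect_equal(r$o_star, -0.6)
  expect_false(r$optimal_flag)
  r <- lmo_coordinate(-1, 0.5, tau = 2)
  expect_equal(r$t_plus, 0)
  expect_equal(r$t_minus, 0.5)
  expect_equal(r$o_star, -0.5)
  # zero gradient: zero measure is optimal
  r0 <- lmo_coordinate(rep(0, 3), c(0.1, 0.5, 0.9), tau = 1)
  expect_true(r0$optimal_flag)
  expect_equal(r0$o_star, 0)
  expect_error(lmo_coordinate(1, 0.5, tau = 0), "tau")
  expect_error(lmo_coordinate(numeric(0), numeric(0), tau = 1), "empty")

  # exactness property: the LMO value is no worse than a 1e5-point grid
  set.seed(22)
  ts <- seq(0, 1, length.out = 1e5)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    x <- runif(n)
    g <- rnorm(n)
    tau <- runif(1, 0.1, 5)
    r <- lmo_coordinate(g, x, tau)
    h <- grid_hinge(g, x, ts)
    best_grid <- (tau / 2) * (min(h) - max(h))
    expect_lte(r$o_star, best_grid + 1e-10)
    # two-point feasibility: TV exactly tau, net mass exactly 0
    if (!r$optimal_flag) {
      s <- atomic_measure(data.frame(coord = 1, t = c(r$t_plus, r$t_minus),
                                     w = c(tau / 2, -tau / 2)))
      expect_identical(tv_norm(s), tau)
      expect_identical(net_mass(s, 1), 0)
    }
  }
})

test_that("lmo ties break to the smallest t and smallest coordinate", {
  # h constant on a flat stretch: argmin must take the smallest candidate
  g <- c(1, -1)
  x <- c(0.2, 0.8)
  r <- lmo_coordinate(g, x, tau = 2)
  expect_equal(r$t_plus, 0)  # h(0) == h(0.2) == -0.6
  # duplicated column: the earlier coordinate wins
  X <- cbind(x, x, x)
  rg <- lmo_gam(g, X, tau = 2)
  expect_equal(rg$coord, 1L)
})

test_that("lmo_gam reduces to lmo_coordinate and scans coordinates", {
  set.seed(23)
  g <- rnorm(10); x <- runif(10)
  r1 <- lmo_coordinate(g, x, tau = 3)
  rg <- lmo_gam(g, matrix(x, ncol = 1), tau = 3)
  expect_equal(rg[c("t_plus", "t_minus", "o_star")],
               r1[c("t_plus", "t_minus", "o_star")])
  # a constant column contributes h == 0 when sum(g) == 0 and never wins
  g0 <- g - mean(g)
  X <- cbind(x, rep(0.5, 10))
  rg <- lmo_gam(g0, X, tau = 3)
  expect_equal(rg$coord, 1L)
  expect_error(lmo_gam(g, matrix(numeric(0), 10, 0), tau = 1), "columns")
})

test_that("duality_gap is the linearized objective difference", {
  g <- c(1, -1); x <- c(0.2, 0.8)
  r <- lmo_coordinate(g, x, tau = 2)
  # mu = 0: gap = 0 - o_star
  expect_equal(duality_gap(g, c(0, 0), r), 0.6)
  # explicit conditional-gradient predictions give the same number
  ps <- (2 / 2) * (pmax(x - r$t_plus, 0) - pmax(x - r$t_minus, 0))
  expect_equal(duality_gap(g, c(0, 0), r, preds_sstar = ps), 0.6)
  # mu = s*: gap = 0
  expect_equal(duality_gap(g, ps, r), sum(g * ps) - r$o_star)
  expect_equal(sum(g * ps), r$o_star)
  # optimality flag forces the zero conditional gradient
  r0 <- lmo_coordinate(rep(0, 2), x, tau = 2)
  expect_equal(duality_gap(rep(0, 2), c(0, 0), r0), 0)
})

test_that("reported gap bounds true suboptimality at every outer iteration", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    X <- matrix(runif(2 * n), n, 2)
    y <- rnorm(n)
    tau <- runif(1, 0.5, 3)
    f <- fit_gam(X, y, loss_spec("squared"),
                 fit_options(tau = tau, tol_gap = 1e-9))
    o <- gridded_oracle(X, y, loss_spec("squared"), tau, tol = 1e-10)
    expect_true(all(f$trace$objective - o$obj <= f$trace$gap + 1e-8))
    expect_true(all(f$trace$gap >= 0))
  }
})
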