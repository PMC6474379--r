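test_that("the two-point interpolation instance is solved exactly", {
  f <- fit_univariate(c(0, 1), c(0, 1), loss_spec("squared"),
                      fit_options(tau = 2))
  expect_lte(f$trace$objective[nrow(f$trace)], 1e-8)
  expect_lte(tv_norm(f$model$measure), 2 * (1 + 1e-9))
  expect_true(f$converged)
})

test_that("tau = 0 returns the analytic constant model for any D", {
  set.seed(41)
  y <- rnorm(20)
  f <- fit_univariate(runif(20), y, loss_spec("squared"), fit_options(tau = 0))
  expect_equal(f$model$intercept, mean(y))
  expect_equal(nrow(f$model$measure$atoms), 0L)
  X <- matrix(runif(60), 20, 3)
  f <- fit_gam(X, y, loss_spec("squared"), fit_options(tau = 0))
  expect_equal(f$model$intercept, mean(y))
  expect_equal(nrow(f$model$measure$atoms), 0L)
  expect_true(f$converged)
})

test_that("fit_gam with D = 1 reproduces fit_univariate exactly", {
  set.seed(42)
  x <- runif(40)
  y <- sin(4 * x) + 0.1 * rnorm(40)
  o <- fit_options(tau = 1.5)
  f1 <- fit_univariate(x, y, loss_spec("squared"), o)
  f2 <- fit_gam(matrix(x, ncol = 1), y, loss_spec("squared"), o)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$measure$atoms, f2$model$measure$atoms)
  expect_identical(f1$model$intercept, f2$model$intercept)
})

test_that("large tau reaches the interpolation limit", {
  set.seed(43)
  x <- sort(runif(30))
  y <- rnorm(30)
  tau <- tv_interpolant(x, y)
  f <- fit_univariate(x, y, loss_spec("squared"),
                      fit_options(tau = tau, tol_gap = 1e-10))
  mse <- mean((predict(f, matrix(x, ncol = 1)) - y)^2)
  expect_lte(mse, 1e-6)
})

test_that("fitted models satisfy all feasibility invariants", {
  set.seed(44)
  losses <- list(loss_spec("squared"), loss_spec("logistic"),
                 loss_spec("pseudo_huber"))
  for (rep in 1:6) {
    n <- sample(15:40, 1)
    D <- sample(1:3, 1)
    X <- matrix(rnorm(n * D), n, D)  # raw features outside [0,1]
    loss <- losses[[1 + rep %% 3]]
    y <- if (loss$kind == "logistic") sample(c(-1, 1), n, TRUE) else rnorm(n)
    tau <- runif(1, 0.2, 4)
    f <- fit_gam(X, y, loss, fit_options(tau = tau))
    expect_feasible_model(f$model, tau)
    # knot support on {0} U {scaled training values} per coordinate
    Xs <- scale_apply(f$model$scaling, X)
    a <- f$model$measure$atoms
    for (k in seq_len(nrow(a))) {
      expect_true(a$t[k] %in% c(0, Xs[, a$coord[k]]))
    }
    # trace invariants
    expect_true(all(diff(f$trace$objective) <= 0))
    expect_true(all(f$trace$gap >= -1e-12))
    if (f$converged) {
      expect_lte(f$final_gap,
                 f$options$tol_gap *
                   max(1, abs(f$trace$objective[nrow(f$trace)])))
    }
  }
})

test_that("warm-started paths are coherent and match cold starts", {
  set.seed(45)
  n <- 60
  X <- matrix(runif(2 * n), n, 2)
  y <- 2 * pmax(X[, 1] - 0.5, 0) - pmax(X[, 1] - 0.2, 0) + 0.05 * rnorm(n)
  taus <- c(0.1, 0.3, 1, 3)
  p <- fit_path(X, y, loss_spec("squared"), taus, fit_options(tol_gap = 1e-8))
  expect_true(all(diff(p$summary$objective) <= 1e-12))
  expect_identical(p$summary$tau, taus)
  for (k in seq_along(taus)) {
    cold <- fit_gam(X, y, loss_spec("squared"),
                    fit_options(tau = taus[k], tol_gap = 1e-8))
    ow <- p$summary$objective[k]
    oc <- cold$trace$objective[nrow(cold$trace)]
    expect_lte(abs(ow - oc), 1e-5 * max(1, abs(oc)))
  }
  expect_error(fit_path(X, y, taus = c(2, 1)), "increasing")
  # a single tau equals fit_gam
  p1 <- fit_path(X, y, loss_spec("squared"), taus = 1,
                 options = fit_options(tol_gap = 1e-8))
  f1 <- fit_gam(X, y, loss_spec("squared"), fit_options(tau = 1, tol_gap = 1e-8))
  expect_equal(p1$summary$objective, f1$trace$objective[nrow(f1$trace)])
})

test_that("default_tau_grid is geometric with the documented span", {
  set.seed(46)
  X <- matrix(runif(100), ncol = 1)
  y <- rnorm(100)
  g <- default_tau_grid(X, y)
  expect_length(g, 16L)
  expect_true(all(diff(g) > 0))
  expect_equal(g[16] / g[1], 1000, tolerance = 1e-9)
  ratios <- g[-1] / g[-16]
  expect_lte(diff(range(ratios)), 1e-9)
})

test_that("refine_knots never increases the objective or breaks feasibility", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 30
    x <- runif(n)
    y <- pmax(x - 0.37, 0) - pmax(x - 0.71, 0) + 0.05 * rnorm(n)
    tau <- 1.5
    f <- fit_univariate(x, y, loss_spec("squared"),
                        fit_options(tau = tau, tol_gap = 1e-4, max_outer = 8))
    obj0 <- dataset_loss_grad(loss_spec("squared"),
                              predict(f, matrix(x, ncol = 1)), y)$value
    m2 <- refine_knots(f$model, matrix(x, ncol = 1), y, loss_spec("squared"))
    obj2 <- dataset_loss_grad(loss_spec("squared"),
                              eval_spline(m2, matrix(x, ncol = 1)), y)$value
    expect_lte(obj2, obj0 + 1e-12)
    expect_feasible_model(m2, tau, tol_rel = 1e-8)
  }
  # a constant model is returned unchanged
  m0 <- spline_model(atomic_measure(D = 1), intercept = 2)
  expect_identical(refine_knots(m0, matrix(runif(5)), rnorm(5)), m0)
})

test_that("all-identical responses converge immediately under squared loss", {
  f <- fit_univariate(runif(10), rep(3.2, 10), loss_spec("squared"),
                      fit_options(tau = 5))
  expect_equal(f$trace$iter[nrow(f$trace)], 0L)
  expect_equal(f$model$intercept, 3.2)
  expect_true(f$converged)
})
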