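test_that("SCR with V = 0 reproduces ordinary least squares", {
  m <- fit_scr(matrix(c(1, 2, 3), 3, 1), c(2, 4, 6), v_fixed = 0)
  expect_equal(unname(m$a), c(0, 2), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    scr <- fit_scr(X, y, v_fixed = 0)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(unname(scr$a), ols, tolerance = 1e-8)
  }
})

test_that("fixed common regularization equals ridge regression", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  lam <- 0.7
  m <- fit_scr(X, y, v_fixed = lam, intercept = FALSE)
  ref <- solve(crossprod(X) + lam * diag(3), crossprod(X, y))
  expect_equal(unname(m$a), as.numeric(ref), tolerance = 1e-10)
})

test_that("self-consistent iteration keeps signal variables and drops noise", {
  set.seed(42)
  X <- matrix(rnorm(400), 40, 10)
  colnames(X) <- paste0("f", 1:10)
  y <- 3 * X[, 2] - 2 * X[, 7] + rnorm(40, 0, 0.01)
  m <- fit_scr(X, y)
  expect_true(all(c("f2", "f7") %in% m$selected))
  noise_kept <- setdiff(m$selected, c("f2", "f7"))
  expect_lte(length(noise_kept), 2) # at least 6 of 8 noise columns dropped
  # near-zero noise: generating coefficients recovered
  expect_equal(unname(m$a["f2"]), 3, tolerance = 1e-2)
  expect_equal(unname(m$a["f7"]), -2, tolerance = 1e-2)
})

test_that("SCR recovers exact linear models as noise vanishes", {
  set.seed(13)
  X <- matrix(rnorm(200), 40, 5)
  colnames(X) <- paste0("g", 1:5)
  astar <- c(1.5, -0.7, 2.2, 0.9, -1.3)
  y <- drop(X %*% astar) + 4
  m <- fit_scr(X, y)
  expect_equal(unname(m$a[paste0("g", 1:5)]), astar, tolerance = 1e-6)
  expect_equal(unname(m$a["(Intercept)"]), 4, tolerance = 1e-6)
})

test_that("SCR predictions are linear and honour the schema", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X[, 1] + 2 * X[, 3] + rnorm(20, 0, 0.01)
  m <- fit_scr(X, y)
  a0 <- unname(m$a["(Intercept)"])
  x1 <- stats::setNames(rnorm(5), colnames(X))
  x2 <- stats::setNames(rnorm(5), colnames(X))
  expect_equal(predict_scr(m, x1 + x2) - a0,
               (predict_scr(m, x1) - a0) + (predict_scr(m, x2) - a0),
               tolerance = 1e-10)
  # all-zero input returns the intercept
  expect_equal(predict_scr(m, stats::setNames(numeric(5), colnames(X))), a0)
  expect_error(predict_scr(m, c(bad = 1)), "schema")
})

test_that("degenerate SCR inputs raise the contracted errors", {
  X <- matrix(1, 6, 2) # all constant
  expect_error(suppressWarnings(fit_scr(X, rnorm(6))), "empty model")
  expect_error(fit_scr(matrix(rnorm(8), 4, 2), rnorm(4)), "at least 5")
  expect_warning(fit_scr(cbind(a = rnorm(10), b = 1), rnorm(10), v_fixed = 0),
                 "constant")
})

test_that("RBF-SCR interpolates its training points", {
  set.seed(21)
  X <- matrix(rnorm(120), 30, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- X[, 1] - 2 * X[, 2] + 0.5 * rnorm(30)
  scr <- fit_scr(X, y)
  rbf <- fit_rbf_scr(X, y, scr)
  pred <- predict_rbf_scr(rbf, X)
  expect_lt(sqrt(sum((pred - y)^2)), 1e-8 * sqrt(sum(y^2)))
})

test_that("two-center RBF solves the hand-worked 1-D system", {
  # weighted positions 0, 1 with responses 0, 1: Phi = [[0,1],[1,0]],
  # w = (1, 0), so the prediction at 0.5 is 0.5
  scr <- structure(list(selected = "f", a = c("(Intercept)" = 0, f = 1),
                        v = c(f = 0), n_train = 2, n_vars = 1, sigma2 = 0,
                        intercept = TRUE, feature_names = "f"),
                   class = "ao_scr")
  X <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "f"))
  rbf <- fit_rbf_scr(X, c(0, 1), scr)
  expect_equal(rbf$w, c(1, 0), tolerance = 1e-12)
  expect_equal(predict_rbf_scr(rbf, c(f = 0.5)), 0.5, tolerance = 1e-12)
})

test_that("scaling the SCR coefficients leaves RBF training predictions unchanged", {
  set.seed(77)
  X <- matrix(rnorm(25), 5, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rnorm(5)
  base <- structure(list(selected = colnames(X),
                         a = c("(Intercept)" = 0,
                               stats::setNames(runif(5, 0.5, 2), colnames(X))),
                         v = stats::setNames(numeric(5), colnames(X)),
                         n_train = 5, n_vars = 5, sigma2 = 0, intercept = TRUE,
                         feature_names = colnames(X)), class = "ao_scr")
  r1 <- fit_rbf_scr(X, y, base)
  scaled <- base
  scaled$a <- base$a * 3
  r2 <- fit_rbf_scr(X, y, scaled)
  # Phi scales by c and w by 1/c
  expect_equal(r2$w, r1$w / 3, tolerance = 1e-8)
  expect_equal(predict_rbf_scr(r2, X), predict_rbf_scr(r1, X),
               tolerance = 1e-8)
})

test_that("RBF predictions are Lipschitz continuous", {
  set.seed(5)
  X <- matrix(rnorm(60), 15, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- rnorm(15)
  scr <- fit_scr(X, y, v_fixed = 0.1)
  rbf <- fit_rbf_scr(X, y, scr)
  L <- sum(abs(rbf$w)) * max(abs(rbf$feat_weights)) * sqrt(ncol(X))
  x <- stats::setNames(rnorm(4), colnames(X))
  for (i in 1:10) {
    delta <- rnorm(4, 0, 0.1)
    d <- abs(predict_rbf_scr(rbf, x + stats::setNames(delta, names(x))) -
               predict_rbf_scr(rbf, x))
    expect_lte(d, L * sqrt(sum(delta^2)) + 1e-12)
  }
})

test_that("degenerate RBF geometries are rejected at fit time", {
  scr <- structure(list(selected = "f", a = c("(Intercept)" = 0, f = 1),
                        v = c(f = 0), n_train = 2, n_vars = 1, sigma2 = 0,
                        intercept = TRUE, feature_names = "f"),
                   class = "ao_scr")
  expect_error(fit_rbf_scr(matrix(1, 1, 1, dimnames = list(NULL, "f")),
                           1, scr), "2 centers")
  expect_error(fit_rbf_scr(matrix(c(2, 2, 2), 3, 1,
                                  dimnames = list(NULL, "f")),
                           c(1, 2, 3), scr), "distinct")
})

test_that("SCR and RBF models survive a JSON round trip bit-exactly", {
  set.seed(3)
  X <- matrix(rnorm(60), 12, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X[, 2] * 2 + rnorm(12, 0, 0.1)
  scr <- fit_scr(X, y)
  js <- write_model_json(scr)
  back <- read_model_json(js)
  expect_identical(write_model_json(back), js)
  expect_equal(predict_scr(back, X), predict_scr(scr, X), tolerance = 1e-12)

  rbf <- fit_rbf_scr(X, y, scr)
  js2 <- write_model_json(rbf)
  back2 <- read_model_json(js2)
  expect_identical(write_model_json(back2), js2)
  expect_equal(predict_rbf_scr(back2, X), predict_rbf_scr(rbf, X),
               tolerance = 1e-12)
})
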