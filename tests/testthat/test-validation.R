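test_that("ranked splits reproduce the reference set sizes", {
  ds <- syn74()
  sp4 <- rank_and_split(ds, 4)
  expect_length(sp4$train, 59)
  expect_length(sp4$test, 15)
  sp5 <- rank_and_split(ds, 5)
  expect_length(sp5$train, 62)
  expect_length(sp5$test, 12)
  # no overlap, full coverage
  expect_length(intersect(sp4$train$ids, sp4$test$ids), 0)
  expect_setequal(c(sp4$train$ids, sp4$test$ids), ds$ids)
})

test_that("test compounds interleave the training activity range", {
  set.seed(8)
  lg <- runif(10, 0, 6)
  ds <- activity_dataset(paste0("c", 1:10),
                         replicate(10, read_smiles("C", "m"),
                                   simplify = FALSE), lg)
  sp <- rank_and_split(ds, 4)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  # each test value lies strictly inside the train range
  expect_true(all(sp$test$lgk7 > min(sp$train$lgk7)))
  expect_true(all(sp$test$lgk7 < max(sp$train$lgk7)))
  expect_error(rank_and_split(ds[1:3], 4), "too small")
})

test_that("train and test means agree on the synthetic 74-compound set", {
  ds <- syn74()
  for (k in c(4, 5)) {
    sp <- rank_and_split(ds, k)
    expect_lt(abs(mean(sp$train$lgk7) - mean(sp$test$lgk7)), 0.5)
  }
})

test_that("leave-many-out CV is seeded, sized and exact for a perfect oracle", {
  ds <- syn74()[1:30]
  truth <- stats::setNames(ds$lgk7, ds$ids)
  oracle <- function(train) function(test) unname(truth[test$ids])
  cv <- cross_validate_lmo(ds, oracle, n_folds = 20, holdout_frac = 0.2,
                           seed = 4)
  expect_length(cv$assignments, 20)
  for (a in cv$assignments) expect_length(a, round(0.2 * 30))
  expect_equal(cv$pooled$q2_f1, 1)
  expect_equal(cv$pooled$rmsep, 0)
  cv2 <- cross_validate_lmo(ds, oracle, n_folds = 20, holdout_frac = 0.2,
                            seed = 4)
  expect_identical(cv$assignments, cv2$assignments)
  # a failing builder marks folds failed but pooling proceeds
  flaky_count <- 0
  flaky <- function(train) {
    flaky_count <<- flaky_count + 1
    if (flaky_count == 3) stop("boom")
    function(test) unname(truth[test$ids])
  }
  cvf <- cross_validate_lmo(ds, flaky, n_folds = 5, seed = 4)
  expect_equal(cvf$failed, 3L)
  expect_equal(cvf$pooled$rmsep, 0)
})

test_that("metric suite matches a naive-loop oracle to 1e-10", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 3, 2)
    yh <- y + rnorm(n, 0, runif(1, 0.01, 2))
    tm <- mean(y) + rnorm(1, 0, 0.5)
    got <- compute_metrics(y, yh, tm)
    ref <- naive_metrics(y, yh, tm)
    for (f in names(ref)) {
      expect_equal(got[[f]], ref[[f]], tolerance = 1e-10, label = f)
    }
    # |CCC| <= |r| by definition
    expect_lte(abs(got$ccc), abs(sqrt(got$r2)) + 1e-12)
  }
})

test_that("perfect and constant predictions give the textbook metric values", {
  y <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  perfect <- compute_metrics(y, y, mean(y))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_0, 1)
  expect_equal(perfect$q2_f1, 1)
  expect_equal(perfect$q2_f2, 1)
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$sd, 0)

  const <- compute_metrics(y, rep(mean(y), 5), mean(y))
  expect_equal(const$q2_f2, 0)

  hand <- compute_metrics(c(1, 2, 3), c(1, 2, 4), train_mean = 2)
  expect_equal(hand$mae, 1 / 3)
  expect_equal(hand$rmsep, sqrt(1 / 3))
  expect_equal(hand$q2_f1, 0.5)

  # zero observed variance: r2-family undefined, flagged, no error
  degen <- compute_metrics(rep(2, 4), c(1, 2, 3, 2), train_mean = 1)
  expect_true(degen$degenerate)
  expect_true(is.nan(degen$r2))
  expect_false(is.nan(degen$mae))
})

test_that("predictivity grades follow the four-condition rules", {
  y <- seq(0, 6.6, length.out = 12)
  perfect <- compute_metrics(y, y, mean(y))
  v <- classify_predictivity(perfect, delta_lgk7 = 6.6)
  expect_equal(v$grade, "high")
  expect_length(v$failed_conditions, 0)

  # all-low report
  low_rep <- perfect
  low_rep$r2 <- low_rep$r2_0 <- low_rep$r2_0_prime <- 0.3
  low_rep$q2_f1 <- low_rep$q2_f2 <- low_rep$ccc <- 0.3
  low_rep$rm2_avg <- 0.2
  low_rep$delta_rm2 <- 0.1
  low_rep$mae <- 0.20 * 6.6
  low_rep$sd <- (0.30 * 6.6 - low_rep$mae) / 3
  expect_equal(classify_predictivity(low_rep, 6.6)$grade, "low")

  # strong correlations but excessive MAE: moderate
  mid <- perfect
  mid$mae <- 0.12 * 6.6
  v2 <- classify_predictivity(mid, 6.6)
  expect_equal(v2$grade, "moderate")
  expect_true("mae" %in% v2$failed_conditions)
})
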