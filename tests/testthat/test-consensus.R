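# a compact training set reused across consensus tests
consensus_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- syn74()[seq(1, 74, by = 2)] # 37 compounds, still spans the range
      model <- suppressWarnings(build_consensus(ds, "qna", seed = 3))
      cache <<- list(ds = ds, model = model)
    }
    cache
  }
})

test_that("single-type ensembles hold exactly 20 partials, combined 320", {
  fx <- consensus_fixture()
  expect_equal(fx$model$n_partials, 20L)
  expect_length(fx$model$partials, 20L)
  expect_true(all(vapply(fx$model$partials, `[[`, "", "descriptor_type") == "qna"))

  ds12 <- syn74()[seq(1, 74, by = 6)]
  cfg <- ao_config()
  mc <- suppressWarnings(build_consensus(ds12, "combined", seed = 3,
                                         config = cfg))
  expect_equal(mc$n_partials, 320L)
  types <- vapply(mc$partials, `[[`, "", "descriptor_type")
  expect_equal(sum(types == "qna"), 160L)
  expect_equal(sum(types == "mna"), 160L)
  # manifest carries the same counts
  manifest <- jsonlite::fromJSON(write_model_json(mc), simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  expect_length(manifest$partials, 320L)
})

test_that("ensembles are bit-identical under the same master seed", {
  fx <- consensus_fixture()
  again <- suppressWarnings(build_consensus(fx$ds, "qna", seed = 3))
  expect_identical(write_model_json(fx$model), write_model_json(again))
  other <- suppressWarnings(build_consensus(fx$ds, "qna", seed = 4))
  expect_false(identical(write_model_json(fx$model), write_model_json(other)))
})

test_that("consensus prediction is the partial mean with sd spread", {
  fx <- consensus_fixture()
  x <- descriptor_matrix(fx$model$featurizer, fx$ds$molecules[1:3])
  per_partial <- vapply(fx$model$partials, function(p) {
    predict_rbf_scr(p$rbf, x[, p$features, drop = FALSE])
  }, numeric(3))
  pred <- predict_consensus(fx$model, x)
  expect_equal(pred$lgk7_pred, rowMeans(per_partial), tolerance = 1e-12)
  pop_sd <- apply(per_partial, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_equal(pred$spread, pop_sd, tolerance = 1e-12)
  # spread convention: two partials predicting 1 and 3 would give spread 1
  expect_equal(sqrt(mean((c(1, 3) - 2)^2)), 1)
  # mean lies within the partial prediction envelope
  expect_true(all(pred$lgk7_pred >= apply(per_partial, 1, min) - 1e-12))
  expect_true(all(pred$lgk7_pred <= apply(per_partial, 1, max) + 1e-12))
  # permutation invariance over partials
  shuffled <- fx$model
  set.seed(1)
  shuffled$partials <- shuffled$partials[sample(20)]
  expect_equal(predict_consensus(shuffled, x)$lgk7_pred, pred$lgk7_pred,
               tolerance = 1e-12)
})

test_that("applicability domain flags training points in and gross outliers out", {
  fx <- consensus_fixture()
  X <- fx$model$ad$X
  ad_train <- applicability_domain(fx$model, X)
  # training points overwhelmingly in-domain (the similarity cutoff is the
  # training 95th percentile, so a few boundary compounds may fall outside)
  expect_gte(mean(ad_train$similarity_ok), 0.9)
  expect_true(all(ad_train$in_domain ==
                    (ad_train$similarity_ok & ad_train$leverage_ok &
                       ad_train$accuracy_ok)))
  # the training centroid has leverage 1/n
  ctr <- matrix(fx$model$ad$centroid, 1,
                dimnames = list("ctr", colnames(X)))
  expect_true(applicability_domain(fx$model, ctr)$leverage_ok)
  # a point at 100x the training scale is flagged dissimilar
  out <- X[1, , drop = FALSE] * 100
  verdict <- applicability_domain(fx$model, out)
  expect_false(verdict$similarity_ok)
  expect_false(verdict$in_domain)
})

test_that("insufficient or malformed training inputs error", {
  ds <- syn74()[1:8]
  expect_error(build_consensus(ds, "qna"), "insufficient")
  expect_error(build_consensus(syn74()[1:12], "nope"), "arg")
})

test_that("noise-free activity linear in descriptors is recovered with R2 >= 0.95", {
  ds <- syn74()
  fz <- fit_featurizer(ds$molecules)
  X <- descriptor_matrix(fz, ds$molecules)
  # linear synthetic response over two whole-molecule descriptors
  y <- 2 + 0.9 * X[, "topological_volume"] + 0.5 * X[, "lipophilicity"]
  lin <- activity_dataset(ds$ids, ds$molecules, y)
  sp <- rank_and_split(lin, 4)
  m <- suppressWarnings(build_consensus(sp$train, "qna", seed = 11))
  pred <- predict_consensus(m, sp$test$molecules)
  r2 <- cor(pred$lgk7_pred, sp$test$lgk7)^2
  expect_gte(r2, 0.95)
})

test_that("serialized consensus models reload without loss", {
  fx <- consensus_fixture()
  f <- tempfile(fileext = ".json")
  write_model_json(fx$model, f)
  back <- read_model_json(f)
  x <- fx$ds$molecules[1:4]
  expect_equal(predict_consensus(back, x)$lgk7_pred,
               predict_consensus(fx$model, x)$lgk7_pred, tolerance = 1e-10)
  expect_equal(applicability_domain(back, x), applicability_domain(fx$model, x))
})
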