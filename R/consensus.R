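#' Build a consensus ensemble of partial RBF-SCR models
#'
#' Fits 20 partial regressions for a single descriptor type (`qna` or
#' `mna`) or 320 (160 per type) for `combined`. Partials are built
#' independently of each other: each one draws a bootstrap resample of
#' the training compounds and a random 50% subset of the type-specific
#' features (the whole-molecule descriptors are always added as
#' candidates), runs SCR variable selection and fits an RBF-SCR
#' interpolator on the SCR-weighted coordinates. Child seeds are derived
#' deterministically from the master seed, so the same seed rebuilds a
#' bit-identical ensemble. The final prediction is the arithmetic mean of
#' the partial predictions.
#'
#' Applicability-domain reference quantities are stored alongside: the
#' training descriptor matrix, the training distribution of the mean
#' distance to the `ad_knn` nearest neighbours, the leverage matrix, and
#' per-compound out-of-bag absolute residuals (each partial predicts the
#' compounds its bootstrap missed).
#'
#' @param train An `ao_dataset` with at least 10 compounds.
#' @param descriptor_type `"qna"`, `"mna"` or `"combined"`.
#' @param seed Master seed.
#' @param config An [ao_config()].
#' @return Object of class `ao_consensus`.
#' @export
build_consensus <- function(train, descriptor_type = c("qna", "mna", "combined"),
                            seed = 1L, config = ao_config()) {
  descriptor_type <- match.arg(descriptor_type)
  if (!inherits(train, "ao_dataset")) stop("train must be an ao_dataset")
  n <- length(train)
  if (n < 10) stop("insufficient data: need at least 10 training compounds")
  stats_tr <- dataset_stats(train)
  if (stats_tr$delta <= 6) {
    warning("training activity range delta lgk7 = ",
            sprintf("%.2f", stats_tr$delta),
            " <= 6; models may not extrapolate reliably")
  }
  y <- train$lgk7
  fz <- fit_featurizer(train$molecules, config = config)
  X <- descriptor_matrix(fz, train$molecules)
  kinds <- attr(X, "kinds")
  wm_feats <- colnames(X)[kinds %in% c("whole_molecule", "physchem")]
  pools <- list(qna = colnames(X)[kinds == "qna_chebyshev"],
                mna = colnames(X)[kinds == "mna_count"])

  if (descriptor_type == "combined") {
    n_partials <- config$n_partials_combined
    types <- rep(c("qna", "mna"), each = n_partials / 2)
  } else {
    n_partials <- config$n_partials
    types <- rep(descriptor_type, n_partials)
  }
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_partials)

  partials <- vector("list", n_partials)
  oob_abs_sum <- oob_cnt <- numeric(n)
  for (j in seq_len(n_partials)) {
    partials[[j]] <- fit_partial(X, y, types[j], pools[[types[j]]], wm_feats,
                                 child_seeds[j], config)
    oob <- partials[[j]]$oob
    if (length(oob$idx) > 0) {
      oob_abs_sum[oob$idx] <- oob_abs_sum[oob$idx] + abs(oob$resid)
      oob_cnt[oob$idx] <- oob_cnt[oob$idx] + 1
    }
  }
  if (config$prune_degenerate) {
    keep <- vapply(partials, function(p) p$train_r2 >= 0, logical(1))
    if (any(keep)) {
      partials <- partials[keep]
      n_partials <- length(partials)
    }
  }

  train_pred <- rowMeans(vapply(partials, function(p) {
    predict_rbf_scr(p$rbf, X)
  }, numeric(n)))
  rmse_train <- sqrt(mean((train_pred - y)^2))
  cv_resid <- ifelse(oob_cnt > 0, oob_abs_sum / pmax(oob_cnt, 1),
                     abs(train_pred - y))

  # similarity reference: leave-self-out mean distance to k nearest
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  k <- min(config$ad_knn, n - 1)
  knn_mean <- apply(D, 1, function(d) mean(sort(d)[seq_len(k)]))
  # leverage: centered cross-product pseudo-inverse
  centroid <- colMeans(X)
  Xc <- sweep(X, 2, centroid)
  G <- pinv(crossprod(Xc))
  p_eff <- qr(Xc)$rank + 1

  structure(list(
    descriptor_type = descriptor_type,
    n_partials = n_partials,
    partials = partials,
    featurizer = fz,
    seed = seed,
    config = config,
    ids = train$ids,
    y = y,
    train_pred = train_pred,
    training_range = c(min = stats_tr$min, max = stats_tr$max),
    ad = list(
      X = X,
      knn_mean = knn_mean,
      sim_threshold = stats::quantile(knn_mean, config$ad_sim_quantile,
                                      names = FALSE),
      centroid = centroid,
      G = G,
      p_eff = p_eff,
      n = n,
      leverage_threshold = config$ad_leverage_factor * p_eff / n,
      cv_resid = cv_resid,
      rmse_train = rmse_train,
      accuracy_threshold = config$ad_accuracy_factor * rmse_train,
      knn = k
    )
  ), class = "ao_consensus")
}

# one partial model: bootstrap rows + random feature subset + SCR + RBF
fit_partial <- function(X, y, type, pool, wm_feats, seed, config) {
  n <- nrow(X)
  set.seed(seed)
  rows <- sort(sample.int(n, n, replace = TRUE))
  urows <- unique(rows)
  n_sub <- max(1L, ceiling(config$feature_frac * length(pool)))
  feats <- c(sort(sample(pool, n_sub)), wm_feats)
  Xb <- X[urows, feats, drop = FALSE]
  yb <- y[urows]
  scr <- tryCatch(
    suppressWarnings(fit_scr(Xb, yb, max_iter = config$scr_max_iter,
                             drop_threshold = config$scr_drop_threshold)),
    error = function(e) NULL)
  if (is.null(scr)) {
    # fall back to keeping all variables (no t-ratio dropping)
    scr <- suppressWarnings(fit_scr(Xb, yb, max_iter = config$scr_max_iter,
                                    drop_threshold = 0))
  }
  rbf <- fit_rbf_scr(Xb, yb, scr)
  fitted <- predict_rbf_scr(rbf, Xb)
  train_r2 <- if (stats::var(yb) > 0) {
    1 - sum((yb - fitted)^2) / sum((yb - mean(yb))^2)
  } else 0
  oob_idx <- setdiff(seq_len(n), urows)
  oob <- list(idx = oob_idx, resid = numeric(0))
  if (length(oob_idx) > 0) {
    oob$resid <- predict_rbf_scr(rbf, X[oob_idx, feats, drop = FALSE]) -
      y[oob_idx]
  }
  list(descriptor_type = type, features = feats, seed = seed,
       scr = scr, rbf = rbf, train_r2 = train_r2, oob = oob)
}

#' @export
print.ao_consensus <- function(x, ...) {
  cat("<ao_consensus> ", x$descriptor_type, ", ", x$n_partials,
      " partials, ", length(x$ids), " training compounds, RMSE(train) = ",
      signif(x$ad$rmse_train, 3), "\n", sep = "")
  invisible(x)
}

# molecules / descriptor rows -> descriptor matrix in model schema
consensus_features <- function(model, x) {
  if (inherits(x, "ao_molecule")) x <- list(x)
  if (is.list(x)) x <- descriptor_matrix(model$featurizer, x)
  align_features(x, colnames(model$ad$X))
}

#' Predict activity with a consensus model
#'
#' The prediction is the arithmetic mean of the partial-model predictions
#' and the spread their standard deviation (population form, n
#' denominator: two partials predicting 1.0 and 3.0 give spread 1.0).
#'
#' @param model An `ao_consensus`.
#' @param x An `ao_molecule`, list of molecules, or descriptor matrix/row
#'   in the model's feature schema.
#' @return data.frame with columns `lgk7_pred` and `spread` (one row per
#'   input).
#' @export
predict_consensus <- function(model, x) {
  feats <- consensus_features(model, x)
  preds <- vapply(model$partials, function(p) {
    predict_rbf_scr(p$rbf, feats[, p$features, drop = FALSE])
  }, numeric(nrow(feats)))
  if (nrow(feats) == 1) preds <- matrix(preds, nrow = 1)
  data.frame(
    lgk7_pred = rowMeans(preds),
    spread = apply(preds, 1, function(r) sqrt(mean((r - mean(r))^2))),
    row.names = rownames(feats)
  )
}

#' Applicability-domain verdict
#'
#' Three independent checks, all always computed:
#' * similarity: the mean Euclidean distance to the `ad_knn` nearest
#'   training vectors must not exceed the training set's own
#'   `ad_sim_quantile` quantile of that statistic;
#' * leverage: the hat value `h = 1/n + (x - c)' (Xc'Xc)^- (x - c)` must
#'   not exceed `3 p / n`;
#' * accuracy: the mean absolute out-of-bag residual of the `ad_knn`
#'   nearest training compounds must not exceed `2 RMSE(train)`.
#' A prediction is in-domain when all three hold.
#'
#' @param model An `ao_consensus`.
#' @param x Molecule(s) or descriptor row(s), as in [predict_consensus()].
#' @return data.frame with logical columns `similarity_ok`, `leverage_ok`,
#'   `accuracy_ok`, `in_domain`.
#' @export
applicability_domain <- function(model, x) {
  feats <- consensus_features(model, x)
  ad <- model$ad
  out <- data.frame(similarity_ok = logical(nrow(feats)),
                    leverage_ok = logical(nrow(feats)),
                    accuracy_ok = logical(nrow(feats)),
                    in_domain = logical(nrow(feats)),
                    row.names = rownames(feats))
  for (i in seq_len(nrow(feats))) {
    xi <- feats[i, ]
    d <- sqrt(colSums((t(ad$X) - xi)^2))
    nn <- order(d)[seq_len(ad$knn)]
    sim_ok <- mean(d[nn]) <= ad$sim_threshold
    xc <- xi - ad$centroid
    h <- 1 / ad$n + as.numeric(t(xc) %*% ad$G %*% xc)
    lev_ok <- h <= ad$leverage_threshold
    acc_ok <- mean(ad$cv_resid[nn]) <= ad$accuracy_threshold
    out[i, ] <- c(sim_ok, lev_ok, acc_ok, sim_ok && lev_ok && acc_ok)
  }
  out
}

#' Predict with applicability-domain flags
#'
#' Convenience wrapper combining [predict_consensus()] and
#' [applicability_domain()].
#'
#' @param model An `ao_consensus`.
#' @param mols Molecule(s) or descriptor rows.
#' @return data.frame: `id`, `lgk7_pred`, `spread`, `similarity_ok`,
#'   `leverage_ok`, `accuracy_ok`, `in_domain`.
#' @export
ao_predict <- function(model, mols) {
  pred <- predict_consensus(model, mols)
  ad <- applicability_domain(model, mols)
  cbind(data.frame(id = rownames(pred)), pred, ad, row.names = NULL)
}
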