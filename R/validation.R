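#' Activity dataset
#'
#' Bundles compound ids, parsed molecules and observed lgk7 values (log10
#' of the rate constant k7 for reaction with peroxyl radicals,
#' L mol^-1 s^-1).
#'
#' @param ids Character vector of compound ids.
#' @param molecules List of `ao_molecule` (same length/order).
#' @param lgk7 Numeric vector of observed lgk7.
#' @return Object of class `ao_dataset`.
#' @export
activity_dataset <- function(ids, molecules, lgk7) {
  stopifnot(length(ids) == length(molecules), length(ids) == length(lgk7))
  if (any(!is.finite(lgk7))) stop("lgk7 must be finite")
  structure(list(ids = as.character(ids), molecules = molecules,
                 lgk7 = as.numeric(lgk7)),
            class = "ao_dataset")
}

#' @export
length.ao_dataset <- function(x) length(x$ids)

#' @export
`[.ao_dataset` <- function(x, i) {
  activity_dataset(x$ids[i], x$molecules[i], x$lgk7[i])
}

#' @export
print.ao_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat("<ao_dataset> ", length(x), " compounds, lgk7 ",
      sprintf("%.2f..%.2f (mean %.2f, sd %.2f, delta %.2f)",
              s$min, s$max, s$mean, s$sd, s$delta), "\n", sep = "")
  invisible(x)
}

#' Summary statistics of a dataset's activities
#'
#' @param ds An `ao_dataset`.
#' @return List with `n`, `min`, `max`, `mean`, `sd` and the activity
#'   range `delta` (max - min). A range above 6 log units is the working
#'   requirement for a reliable training set.
#' @export
dataset_stats <- function(ds) {
  list(n = length(ds), min = min(ds$lgk7), max = max(ds$lgk7),
       mean = mean(ds$lgk7), sd = stats::sd(ds$lgk7),
       delta = max(ds$lgk7) - min(ds$lgk7))
}

round_half_up <- function(x) floor(x + 0.5)

#' Rank-ordered train/test split
#'
#' Compounds are ranked by increasing lgk7 (stable sort; input order
#' breaks ties) and every (k+1)-th position of the ranked list -- evenly
#' spaced at positions `ceiling((i - 0.5) n / n_test)` -- is transferred
#' to the test set, so both sets span the activity range uniformly. The
#' test-set size is `n/(k+1)` rounded half-up: for 74 compounds a 4:1
#' split gives 59 train / 15 test and a 5:1 split 62/12.
#'
#' @param ds An `ao_dataset`.
#' @param ratio_k Train:test ratio k (k:1), `>= 1`.
#' @return List with `train` and `test` datasets (both in rank order).
#' @export
rank_and_split <- function(ds, ratio_k = 4L) {
  stopifnot(ratio_k >= 1)
  n <- length(ds)
  if (n < ratio_k + 1) stop("dataset too small for a ", ratio_k, ":1 split")
  ord <- order(ds$lgk7) # stable in R
  ranked <- ds[ord]
  n_test <- round_half_up(n / (ratio_k + 1))
  pos <- unique(pmin(ceiling((seq_len(n_test) - 0.5) * n / n_test), n))
  list(train = ranked[setdiff(seq_len(n), pos)], test = ranked[pos])
}

#' Leave-many-out cross-validation
#'
#' Repeated random holdout: `n_folds` independent splits each releasing
#' `holdout_frac` of the compounds, the model rebuilt on the remainder
#' each time. Fold membership is seeded and reproducible. The pooled
#' report concatenates all held-out predictions.
#'
#' @param ds An `ao_dataset`.
#' @param build Model builder: a function taking a training `ao_dataset`
#'   and returning a prediction function (test `ao_dataset` -> numeric).
#' @param n_folds Number of random folds (default 20).
#' @param holdout_frac Released fraction per fold (default 0.20).
#' @param seed Integer seed.
#' @return List: `folds` (per-fold `ao_validation_report`, NULL for failed
#'   folds), `pooled` (report over concatenated holdouts), `failed`
#'   (indices of failed folds), `assignments` (list of holdout index
#'   vectors).
#' @export
cross_validate_lmo <- function(ds, build, n_folds = 20L, holdout_frac = 0.20,
                               seed = 1L) {
  n <- length(ds)
  if (n < 10) stop("need at least 10 compounds for cross-validation")
  n_out <- max(1L, round_half_up(n * holdout_frac))
  set.seed(seed)
  assignments <- lapply(seq_len(n_folds), function(i) sort(sample.int(n, n_out)))
  folds <- vector("list", n_folds)
  failed <- integer(0)
  obs_all <- pred_all <- numeric(0)
  tmean_all <- numeric(0)
  for (i in seq_len(n_folds)) {
    hold <- assignments[[i]]
    train <- ds[-hold]; test <- ds[hold]
    res <- tryCatch({
      predictor <- build(train)
      pred <- predictor(test)
      list(pred = pred, tmean = mean(train$lgk7))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      next
    }
    folds[[i]] <- compute_metrics(test$lgk7, res$pred, res$tmean)
    obs_all <- c(obs_all, test$lgk7)
    pred_all <- c(pred_all, res$pred)
    tmean_all <- c(tmean_all, rep(res$tmean, length(hold)))
  }
  if (length(failed) == n_folds) stop("all cross-validation folds failed")
  pooled <- compute_metrics(obs_all, pred_all, mean(tmean_all))
  list(folds = folds, pooled = pooled, failed = failed,
       assignments = assignments)
}

#' External-validation metric suite
#'
#' Computes, for one (observed, predicted) pairing:
#' determination coefficient `r2`; through-origin determination
#' coefficients `r2_0` (predicted regressed on observed) and
#' `r2_0_prime` (observed on predicted); external predictivity
#' `q2_f1 = 1 - RSS / sum (y - mean(y_train))^2` and
#' `q2_f2 = 1 - RSS / sum (y - mean(y_test))^2`; the rm2 metrics
#' `rm2 = r2 (1 - sqrt(|r2 - r2_0|))` and its primed counterpart, with
#' their average and absolute difference; Lin's concordance correlation
#' coefficient `ccc`; and the error metrics `rmsep`, `mae` and `sd` (the
#' n-1 standard deviation of the absolute errors). A systematic-error
#' flag is raised when the mean signed residual exceeds
#' `2 rmsep / sqrt(n)`.
#'
#' With zero variance in the observations the r2-family is undefined and
#' reported as NaN with `degenerate = TRUE` (no error is thrown).
#'
#' @param y_obs Observed values (length >= 3).
#' @param y_pred Predicted values.
#' @param train_mean Mean activity of the training set (for Q2F1).
#' @return Object of class `ao_validation_report`.
#' @export
compute_metrics <- function(y_obs, y_pred, train_mean) {
  n <- length(y_obs)
  stopifnot(length(y_pred) == n, n >= 3, is.finite(train_mean))
  err <- y_obs - y_pred
  rss <- sum(err^2)
  rmsep <- sqrt(rss / n)
  mae <- mean(abs(err))
  sd_abs <- stats::sd(abs(err))
  degenerate <- stats::var(y_obs) == 0
  if (degenerate) {
    r2 <- r2_0 <- r2_0p <- q2f2 <- ccc <- NaN
  } else if (stats::var(y_pred) == 0) {
    # constant predictions: correlation-based members are undefined
    r2 <- r2_0 <- NaN
    kp <- sum(y_obs * y_pred) / sum(y_pred^2)
    r2_0p <- 1 - sum((y_obs - kp * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
    q2f2 <- 1 - rss / sum((y_obs - mean(y_obs))^2)
    ccc <- 0
  } else {
    r2 <- stats::cor(y_obs, y_pred)^2
    # through-origin fits: predicted-on-observed and observed-on-predicted
    k <- sum(y_obs * y_pred) / sum(y_obs^2)
    r2_0 <- 1 - sum((y_pred - k * y_obs)^2) / sum((y_pred - mean(y_pred))^2)
    kp <- sum(y_obs * y_pred) / sum(y_pred^2)
    r2_0p <- 1 - sum((y_obs - kp * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
    q2f2 <- 1 - rss / sum((y_obs - mean(y_obs))^2)
    mx <- mean(y_obs); my <- mean(y_pred)
    sxy <- mean((y_obs - mx) * (y_pred - my))
    ccc <- 2 * sxy / (mean((y_obs - mx)^2) + mean((y_pred - my)^2) +
                        (mx - my)^2)
  }
  q2f1 <- 1 - rss / sum((y_obs - train_mean)^2)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r2_0)))
  rm2p <- r2 * (1 - sqrt(abs(r2 - r2_0p)))
  structure(list(
    r2 = r2, r2_0 = r2_0, r2_0_prime = r2_0p,
    q2_f1 = q2f1, q2_f2 = q2f2,
    rm2 = rm2, rm2_prime = rm2p,
    rm2_avg = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p),
    ccc = ccc, rmsep = rmsep, mae = mae, sd = sd_abs, n = n,
    systematic_error = abs(mean(err)) > 2 * rmsep / sqrt(n),
    degenerate = degenerate
  ), class = "ao_validation_report")
}

#' @export
print.ao_validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation report> n=%d  R2=%.3f  R2_0=%.3f  Q2F1=%.3f  Q2F2=%.3f\n",
    x$n, x$r2, x$r2_0, x$q2_f1, x$q2_f2))
  cat(sprintf("  rm2(avg)=%.3f  drm2=%.3f  CCC=%.3f  RMSEP=%.3f  MAE=%.3f  SD=%.3f\n",
              x$rm2_avg, x$delta_rm2, x$ccc, x$rmsep, x$mae, x$sd))
  if (isTRUE(x$systematic_error)) cat("  [systematic error flagged]\n")
  invisible(x)
}

#' Predictivity grade of a validation report
#'
#' Applies the four high-predictivity conditions: (1) all determination
#' coefficients (r2, r2_0, r2_0', Q2F1, Q2F2 and CCC) close to each other
#' and tending to unity -- operationalized as every value >=
#' `high_floor` (0.85) with pairwise spread <= `high_spread` (0.1);
#' (2) rm2(avg) > 0.5 with delta rm2 < 0.2; (3) MAE <= 10% of the
#' training activity range; (4) MAE + 3 SD <= 20% of the range. The
#' mirrored low-predictivity conditions use a 0.6 ceiling, rm2 <= 0.5
#' with delta <= 0.2, MAE > 15% and MAE + 3 SD > 25%. A model meeting all
#' four high conditions is graded `high`; all four low conditions,
#' `low`; anything else `moderate`.
#'
#' @param report An `ao_validation_report`.
#' @param delta_lgk7 Activity range (max - min) of the training set.
#' @param high_floor,high_spread Operationalization of "close to each
#'   other and tend to unity" for the high grade.
#' @return List of class `ao_predictivity` with `grade` (high / moderate /
#'   low) and `failed_conditions` (the high conditions not met).
#' @export
classify_predictivity <- function(report, delta_lgk7, high_floor = 0.85,
                                  high_spread = 0.1) {
  stopifnot(delta_lgk7 > 0)
  dets <- c(r2 = report$r2, r2_0 = report$r2_0, r2_0_prime = report$r2_0_prime,
            q2_f1 = report$q2_f1, q2_f2 = report$q2_f2, ccc = report$ccc)
  dets_ok <- all(is.finite(dets)) && all(dets >= high_floor) &&
    (max(dets) - min(dets)) <= high_spread
  rm2_ok <- is.finite(report$rm2_avg) && report$rm2_avg > 0.5 &&
    report$delta_rm2 < 0.2
  mae_ok <- report$mae <= 0.10 * delta_lgk7
  mae3sd_ok <- (report$mae + 3 * report$sd) <= 0.20 * delta_lgk7
  high_checks <- c(determination_coefficients = dets_ok, rm2 = rm2_ok,
                   mae = mae_ok, mae_plus_3sd = mae3sd_ok)
  low <- all(is.finite(dets)) && all(dets <= 0.6) &&
    is.finite(report$rm2_avg) && report$rm2_avg <= 0.5 &&
    report$delta_rm2 <= 0.2 &&
    report$mae > 0.15 * delta_lgk7 &&
    (report$mae + 3 * report$sd) > 0.25 * delta_lgk7
  grade <- if (all(high_checks)) "high" else if (low) "low" else "moderate"
  structure(list(grade = grade,
                 failed_conditions = names(high_checks)[!high_checks]),
            class = "ao_predictivity")
}

#' @export
print.ao_predictivity <- function(x, ...) {
  cat("<predictivity> grade:", x$grade)
  if (length(x$failed_conditions) > 0) {
    cat("  (unmet high conditions:",
        paste(x$failed_conditions, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}
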