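#' Pipeline configuration
#'
#' Collects every tunable of the modeling pipeline with its default.
#' Defaults mirror the modeled study design where one is stated there
#' (20 partial regressions per single-descriptor consensus, 320 for the
#' combined one, 20-fold leave-many-out CV releasing 20% of compounds,
#' ranked 4:1 / 5:1 splits); the remaining values are documented package
#' choices.
#'
#' @param cheb_degree Maximum total degree m+n of the 2-D Chebyshev
#'   features built from the squashed QNA P/Q values (15 features at 4).
#' @param mna_level Deepest MNA neighborhood level (0 = atom marks only).
#' @param qna_exponential `"matrix"` (matrix exponential of -C/2, the
#'   default) or `"elementwise"` (entry-wise exp), see the methods
#'   vignette.
#' @param scr_drop_threshold t-ratio below which SCR drops a variable.
#' @param scr_max_iter Maximum SCR self-consistency iterations.
#' @param n_partials Partial regressions per single-type consensus.
#' @param n_partials_combined Partial regressions in a combined consensus.
#' @param feature_frac Fraction of type-specific features sampled per
#'   partial model.
#' @param prune_degenerate Drop partials whose internal fit is degenerate
#'   (training R2 < 0); off by default (plain averaging of all partials).
#' @param cv_folds,cv_holdout Leave-many-out CV: number of random folds
#'   and the held-out fraction.
#' @param split_ratio Train:test ratio k (k:1) for the ranked split.
#' @param ad_sim_quantile Training quantile of the mean 3-NN distance used
#'   as the similarity cutoff.
#' @param ad_knn Neighbours used by the similarity and accuracy checks.
#' @param ad_leverage_factor Leverage cutoff factor c in h <= c*p/n.
#' @param ad_accuracy_factor Accuracy cutoff factor c in
#'   mean |CV residual| of neighbours <= c*RMSE(train).
#' @param v0,vi,k6 Kinetics defaults: uninhibited oxidation rate,
#'   initiation rate (mol L^-1 s^-1) and peroxyl recombination constant
#'   (L mol^-1 s^-1) typical for initiated ethylbenzene oxidation at 348 K.
#' @return A named list of class `ao_config`.
#' @export
ao_config <- function(cheb_degree = 4L,
                      mna_level = 2L,
                      qna_exponential = c("matrix", "elementwise"),
                      scr_drop_threshold = 2.0,
                      scr_max_iter = 50L,
                      n_partials = 20L,
                      n_partials_combined = 320L,
                      feature_frac = 0.5,
                      prune_degenerate = FALSE,
                      cv_folds = 20L,
                      cv_holdout = 0.20,
                      split_ratio = 4L,
                      ad_sim_quantile = 0.95,
                      ad_knn = 3L,
                      ad_leverage_factor = 3,
                      ad_accuracy_factor = 2,
                      v0 = 5e-6,
                      vi = 1e-7,
                      k6 = 1.9e7) {
  cfg <- list(
    cheb_degree = as.integer(cheb_degree),
    mna_level = as.integer(mna_level),
    qna_exponential = match.arg(qna_exponential),
    scr_drop_threshold = scr_drop_threshold,
    scr_max_iter = as.integer(scr_max_iter),
    n_partials = as.integer(n_partials),
    n_partials_combined = as.integer(n_partials_combined),
    feature_frac = feature_frac,
    prune_degenerate = isTRUE(prune_degenerate),
    cv_folds = as.integer(cv_folds),
    cv_holdout = cv_holdout,
    split_ratio = as.integer(split_ratio),
    ad_sim_quantile = ad_sim_quantile,
    ad_knn = as.integer(ad_knn),
    ad_leverage_factor = ad_leverage_factor,
    ad_accuracy_factor = ad_accuracy_factor,
    v0 = v0, vi = vi, k6 = k6
  )
  class(cfg) <- "ao_config"
  cfg
}
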