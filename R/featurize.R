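#' Fit a featurizer on a training set of molecules
#'
#' A featurizer freezes every training-set-dependent quantity of the
#' descriptor pipeline: the QNA squashing scales (median |P|, |Q| over
#' training atoms), the MNA vocabulary, and the Z-score parameters of the
#' whole-molecule block. Applying it to new molecules therefore uses
#' training statistics only.
#'
#' @param mols List of training `ao_molecule`.
#' @param config An [ao_config()].
#' @param props Element property table.
#' @return Object of class `ao_featurizer`.
#' @export
fit_featurizer <- function(mols, config = ao_config(),
                           props = element_properties()) {
  if (length(mols) == 0) stop("empty molecule list")
  qnas <- lapply(mols, compute_qna, props = props,
                 exponential = config$qna_exponential)
  scales <- qna_scale_params(qnas)
  mna <- mna_feature_vector(mols, level = config$mna_level)
  fz <- structure(list(
    config = config,
    s_p = scales$s_p, s_q = scales$s_q,
    vocab = attr(mna, "vocab"),
    norm = NULL,
    feature_names = NULL, kinds = NULL
  ), class = "ao_featurizer")
  raw <- descriptor_matrix(fz, mols, normalized = FALSE, qnas = qnas,
                           mna = mna, props = props)
  fz$norm <- fit_normalization(raw)
  norm_mat <- apply_normalization(raw, fz$norm)
  fz$feature_names <- colnames(norm_mat)
  fz$kinds <- attr(norm_mat, "kinds")
  fz
}

#' Descriptor matrix for a set of molecules
#'
#' Assembles the QNA-Chebyshev, MNA-count and whole-molecule blocks for
#' each molecule using the frozen parameters of a fitted featurizer and,
#' by default, applies the training Z-score normalization.
#'
#' @param fz An `ao_featurizer`.
#' @param mols List of `ao_molecule` (or a single one).
#' @param normalized Apply the stored normalization (default TRUE).
#' @param qnas,mna Internal: precomputed blocks.
#' @param props Element property table.
#' @return Numeric matrix (rows = molecules, rownames = ids) with `kinds`
#'   attribute.
#' @export
descriptor_matrix <- function(fz, mols, normalized = TRUE, qnas = NULL,
                              mna = NULL, props = element_properties()) {
  if (inherits(mols, "ao_molecule")) mols <- list(mols)
  cfg <- fz$config
  if (is.null(qnas)) {
    qnas <- lapply(mols, compute_qna, props = props,
                   exponential = cfg$qna_exponential)
  }
  cheb <- t(vapply(qnas, function(q) {
    chebyshev_features(q, max_degree = cfg$cheb_degree,
                       s_p = fz$s_p, s_q = fz$s_q)
  }, numeric(sum(seq_len(cfg$cheb_degree + 1)))))
  cheb_kinds <- rep("qna_chebyshev", ncol(cheb))
  if (is.null(mna)) {
    mna <- mna_feature_vector(mols, level = cfg$mna_level, vocab = fz$vocab)
  }
  wm <- t(vapply(mols, whole_molecule_descriptors, numeric(10), props = props))
  wm_kinds <- attr(whole_molecule_descriptors(mols[[1]], props), "kinds")
  out <- cbind(cheb, mna, wm)
  rownames(out) <- vapply(mols, `[[`, "", "id")
  attr(out, "kinds") <- c(cheb_kinds, attr(mna, "kinds"), wm_kinds)
  if (normalized) {
    if (is.null(fz$norm)) stop("featurizer has no fitted normalization")
    out <- apply_normalization(out, fz$norm)
  }
  out
}
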