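#' Whole-molecule and physicochemical descriptors
#'
#' Computes the molecule-level descriptors used alongside the atomic ones:
#' * `topological_length` -- the maximal topological distance (bond count)
#'   between any two atoms;
#' * `topological_volume` -- the sum of atomic volumes `4/3 pi R^3`
#'   (Angstrom^3), additive over atoms;
#' * `lipophilicity` -- sum of per-element additive logP increments (an
#'   approximate atom-contribution scheme, shipped with the element
#'   table);
#' plus the physicochemical counts: positive/negative formal charges,
#' hydrogen-bond donors (N/O bearing at least one hydrogen) and acceptors
#' (N/O/F), aromatic atoms, molecular weight (Da) and halogen atoms.
#'
#' @param mol An `ao_molecule`.
#' @param props Element property table.
#' @return Named numeric vector with a `kinds` attribute
#'   (`whole_molecule` for the three molecule descriptors, `physchem` for
#'   the counts).
#' @export
#' @examples
#' whole_molecule_descriptors(read_smiles("c1ccccc1O", "phenol"))
whole_molecule_descriptors <- function(mol, props = element_properties()) {
  el <- mol$atoms$element
  d <- graph_distances(mol)
  vol <- sum(4 / 3 * pi * props[el, "radius"]^3)
  logp <- sum(props[el, "logp_contrib"])
  has_h_neighbor <- vapply(seq_len(n_atoms(mol)), function(i) {
    any(el[mol$connectivity[i, ] == 1] == "H")
  }, logical(1))
  vals <- c(
    topological_length = max(d),
    topological_volume = vol,
    lipophilicity = logp,
    n_pos_charge = sum(mol$atoms$formal_charge > 0),
    n_neg_charge = sum(mol$atoms$formal_charge < 0),
    n_hbd = sum(props[el, "hbd"] & has_h_neighbor),
    n_hba = sum(props[el, "hba"]),
    n_aromatic_atoms = sum(mol$atoms$is_aromatic),
    mol_weight = sum(props[el, "mass"]),
    n_halogen = sum(el %in% c("F", "Cl", "Br", "I"))
  )
  attr(vals, "kinds") <- c(rep("whole_molecule", 3), rep("physchem", 7))
  vals
}

#' Z-score normalization fitted on a training set
#'
#' Only whole-molecule/physchem features are normalized; the QNA-Chebyshev
#' and MNA-count features already live on the [-1, 1] scale and pass
#' through unchanged. Means and standard deviations (population, n
#' denominator) are estimated on the training matrix only; zero-variance
#' features are flagged and dropped from modeling.
#'
#' @param train Numeric training matrix with colnames and a `kinds`
#'   attribute (as produced by [descriptor_matrix()]).
#' @return List of class `ao_norm` with `mean`, `sd`, the normalized
#'   feature names and the dropped zero-variance features.
#' @export
fit_normalization <- function(train) {
  kinds <- attr(train, "kinds")
  if (is.null(kinds)) stop("training matrix lacks a 'kinds' attribute")
  if (nrow(train) < 2) stop("need at least 2 training vectors")
  target <- colnames(train)[kinds %in% c("whole_molecule", "physchem")]
  mu <- colMeans(train[, target, drop = FALSE])
  n <- nrow(train)
  sigma <- sqrt(colMeans(sweep(train[, target, drop = FALSE], 2, mu)^2))
  zero_var <- target[sigma == 0]
  structure(list(mean = mu, sd = sigma, features = target,
                 zero_var = zero_var),
            class = "ao_norm")
}

#' Apply fitted Z-score normalization
#'
#' Transforms the whole-molecule/physchem columns with the training
#' mean/sd and drops the training-set zero-variance columns; all other
#' columns pass through unchanged.
#'
#' @param x Descriptor matrix (or named vector) with the training schema.
#' @param params An `ao_norm` from [fit_normalization()].
#' @return Matrix with normalized columns (zero-variance ones removed).
#' @export
apply_normalization <- function(x, params) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  kinds <- attr(x, "kinds")
  missing <- setdiff(params$features, colnames(x))
  if (length(missing) > 0) {
    stop("schema mismatch: missing feature(s) ", paste(missing, collapse = ", "))
  }
  keep <- setdiff(params$features, params$zero_var)
  x[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2, params$mean[keep]),
                     2, params$sd[keep], "/")
  if (length(params$zero_var) > 0) {
    sel <- !(colnames(x) %in% params$zero_var)
    kinds <- kinds[sel]
    x <- x[, sel, drop = FALSE]
  }
  attr(x, "kinds") <- kinds
  x
}
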