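#' Multilevel Neighbourhoods of Atoms (MNA) descriptors
#'
#' The level-0 MNA descriptor of an atom is its mark: the element symbol,
#' prefixed with `-` when the atom does not belong to a ring. The level-k
#' descriptor is the substructure notation `A(D1 D2 ... Di ...)` where the
#' `Di` are the level-(k-1) descriptors of the immediate neighbours,
#' concatenated in lexicographic order so that the notation is canonical
#' (invariant under atom relabeling). Bond types are not encoded.
#'
#' @param mol An `ao_molecule`.
#' @param level Deepest neighborhood level to generate (>= 0); descriptors
#'   of all levels `0..level` are returned.
#' @return Named integer vector: descriptor notation -> count over all
#'   atoms and levels.
#' @export
#' @examples
#' compute_mna(read_smiles("O", "water"), level = 1)
#' # -H(-O) appears twice, -O(-H-H) once
compute_mna <- function(mol, level = 2L) {
  stopifnot(level >= 0)
  n <- n_atoms(mol)
  marks <- ifelse(mol$atoms$in_ring, mol$atoms$element,
                  paste0("-", mol$atoms$element))
  nbrs <- lapply(seq_len(n), function(i) which(mol$connectivity[i, ] == 1))
  all_desc <- character(0)
  current <- marks
  all_desc <- c(all_desc, current)
  lv <- 0L
  while (lv < level) {
    nxt <- vapply(seq_len(n), function(i) {
      inner <- sort(current[nbrs[[i]]], method = "radix")
      paste0(marks[i], "(", paste0(inner, collapse = ""), ")")
    }, character(1))
    all_desc <- c(all_desc, nxt)
    current <- nxt
    lv <- lv + 1L
  }
  counts <- table(all_desc)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(names(out), method = "radix")]
}

#' MNA count feature matrix for a set of molecules
#'
#' Builds (or reuses) a vocabulary -- the lexicographically ordered union
#' of MNA descriptors over the molecule list -- and maps each molecule to
#' its squashed count vector. Counts x are squashed onto [-1, 1) by
#' `u = x/(1+x)` followed by `2u - 1`, honouring the common descriptor
#' scale without needing a training-set maximum; an absent descriptor
#' (x = 0) maps to -1.
#'
#' @param mols Non-empty list of `ao_molecule`.
#' @param level MNA depth (see [compute_mna()]).
#' @param vocab Optional fixed vocabulary (training-set vocabulary when
#'   featurizing new molecules); descriptors outside it are ignored.
#' @return Numeric matrix, one row per molecule (rownames = molecule ids),
#'   columns `mna:<notation>` with a `kinds` attribute of `"mna_count"`
#'   and the vocabulary as attribute `vocab`.
#' @export
mna_feature_vector <- function(mols, level = 2L, vocab = NULL) {
  if (length(mols) == 0) stop("empty molecule list")
  if (inherits(mols, "ao_molecule")) mols <- list(mols)
  counts <- lapply(mols, compute_mna, level = level)
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(counts, names))), method = "radix")
  }
  mat <- matrix(0, length(mols), length(vocab),
                dimnames = list(vapply(mols, `[[`, "", "id"),
                                paste0("mna:", vocab)))
  for (i in seq_along(mols)) {
    hit <- intersect(names(counts[[i]]), vocab)
    mat[i, paste0("mna:", hit)] <- counts[[i]][hit]
  }
  u <- mat / (1 + mat)
  out <- 2 * u - 1
  attr(out, "kinds") <- rep("mna_count", ncol(out))
  attr(out, "vocab") <- vocab
  out
}
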