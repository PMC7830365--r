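test_that("QNA values match closed forms on one- and two-atom systems", {
  # lone carbon: E = exp(0) = 1, so P = B^2 and Q = B^2 A
  cm <- read_smiles("[C]", "carbon")
  q <- compute_qna(cm)
  expect_equal(q$A, 6.26, tolerance = 1e-12)
  expect_equal(q$B, 10^(-1 / 2), tolerance = 1e-12)
  expect_equal(q$P, 0.100, tolerance = 1e-12)
  expect_equal(q$Q, 0.626, tolerance = 1e-12)
  expect_equal(q$P, q$B^2, tolerance = 1e-14)
  expect_equal(q$Q, q$B^2 * q$A, tolerance = 1e-14)

  # bonded homonuclear pair: E = [[cosh .5, -sinh .5], [-sinh .5, cosh .5]]
  el <- element_properties()["O", ]
  A <- (el$IP + el$EA) / 2
  B <- (el$IP - el$EA)^(-1 / 2)
  mol <- read_smiles("O", "water") # grab an O-H? no: build the pair directly
  pair <- structure(list(
    id = "o2",
    atoms = data.frame(index = 0:1, element = "O", formal_charge = 0L,
                       in_ring = FALSE, is_aromatic = FALSE),
    connectivity = matrix(c(0L, 1L, 1L, 0L), 2)), class = "ao_molecule")
  qp <- compute_qna(pair)
  expect_equal(qp$P[1], B * (cosh(0.5) * B - sinh(0.5) * B), tolerance = 1e-12)
  expect_equal(qp$P[1], B^2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(qp$Q[1], B^2 * A * exp(-0.5), tolerance = 1e-12)
})

test_that("QNA agrees with a scaled-Taylor matrix-exponential oracle", {
  props <- element_properties()
  for (smi in c("CCO", "c1ccccc1", "CC(C)O", "O", "CC#N")) {
    mol <- read_smiles(smi, "x")
    if (n_atoms(mol) > 15) next
    q <- compute_qna(mol)
    el <- mol$atoms$element
    A <- (props[el, "IP"] + props[el, "EA"]) / 2
    B <- (props[el, "IP"] - props[el, "EA"])^(-1 / 2)
    E <- expm_taylor(-0.5 * mol$connectivity)
    expect_equal(q$P, as.numeric(B * (E %*% B)), tolerance = 1e-12)
    expect_equal(q$Q, as.numeric(B * (E %*% (B * A))), tolerance = 1e-12)
  }
})

test_that("QNA P/Q are invariant under atom reindexing", {
  set.seed(11)
  pool <- random_smiles_pool()
  for (smi in sample(pool, 20, replace = TRUE)) {
    mol <- read_smiles(smi, "x")
    q <- compute_qna(mol)
    n <- n_atoms(mol)
    perm <- sample.int(n)
    pmol <- mol
    pmol$atoms <- mol$atoms[perm, ]
    pmol$atoms$index <- seq_len(n) - 1L
    rownames(pmol$atoms) <- NULL
    pmol$connectivity <- mol$connectivity[perm, perm]
    qp <- compute_qna(pmol)
    expect_equal(sort(qp$P), sort(q$P), tolerance = 1e-12)
    expect_equal(sort(qp$Q), sort(q$Q), tolerance = 1e-12)
  }
})

test_that("Chebyshev features obey the [-1, 1] scale and known values", {
  # T0 x T0 is 1 for every molecule
  mols <- test_molecules()
  for (mol in mols) {
    f <- chebyshev_features(compute_qna(mol), max_degree = 4)
    expect_equal(unname(f["cheb_0_0"]), 1)
    expect_true(all(f >= -1 & f <= 1))
    expect_length(f, 15)
  }
  # single atom with squashed P = 0.5, Q = 0: cheb_2_0 = T2(0.5) = -0.5
  qna <- structure(list(A = 1, B = 1, P = tan(pi / 4), Q = 0),
                   class = "ao_qna")
  f <- chebyshev_features(qna, max_degree = 2, s_p = 1, s_q = 1)
  expect_equal(unname(f["cheb_2_0"]), 2 * 0.5^2 - 1, tolerance = 1e-12)
  # bound holds on a wider random pool
  set.seed(5)
  for (smi in sample(random_smiles_pool(), 50, replace = TRUE)) {
    f <- chebyshev_features(compute_qna(read_smiles(smi, "x")), max_degree = 4,
                            s_p = 0.2, s_q = 2)
    expect_true(all(f >= -1 & f <= 1))
  }
})

test_that("MNA descriptors match hand-derived environments", {
  water <- compute_mna(test_molecules()$water, level = 1)
  expect_equal(unname(water["-H(-O)"]), 2)
  expect_equal(unname(water["-O(-H-H)"]), 1)

  methane <- compute_mna(test_molecules()$methane, level = 1)
  expect_equal(unname(methane["-C(-H-H-H-H)"]), 1)

  # level 0 is the atom-mark multiset; ring atoms lack the "-" prefix
  benz0 <- compute_mna(test_molecules()$benzene, level = 0)
  expect_equal(unname(benz0[["C"]]), 6)
  expect_equal(unname(benz0[["-H"]]), 6)
})

test_that("MNA multisets are invariant under relabeling of the same structure", {
  pairs <- list(c("c1ccccc1O", "Oc1ccccc1"),
                c("CC(=O)O", "OC(C)=O"),
                c("O=C1C=CNC(=O)N1", "O=C1NC(=O)C=CN1"))
  for (p in pairs) {
    a <- compute_mna(read_smiles(p[1], "a"), level = 2)
    b <- compute_mna(read_smiles(p[2], "b"), level = 2)
    expect_identical(a, b)
  }
})

test_that("MNA feature vectors squash counts onto [-1, 1)", {
  mols <- list(test_molecules()$water, test_molecules()$water,
               test_molecules()$phenol)
  M <- mna_feature_vector(mols, level = 2)
  expect_true(all(M >= -1 & M < 1))
  expect_equal(M[1, ], M[2, ]) # identical molecules, identical vectors
  # a descriptor absent from a molecule maps to exactly -1
  expect_true(any(M[1, ] == -1))
  expect_error(mna_feature_vector(list()), "empty")
})

test_that("whole-molecule descriptors match hand-computed values", {
  # lone carbon: volume only
  f <- whole_molecule_descriptors(read_smiles("[C]", "c"))
  expect_equal(unname(f["topological_length"]), 0)
  expect_equal(unname(f["topological_volume"]), 4 / 3 * pi * 1.70^3,
               tolerance = 1e-12)

  benz <- whole_molecule_descriptors(test_molecules()$benzene)
  expect_equal(unname(benz["n_aromatic_atoms"]), 6)
  expect_equal(unname(benz["n_halogen"]), 0)
  expect_equal(unname(benz["n_pos_charge"]), 0)
  expect_equal(unname(benz["n_neg_charge"]), 0)

  ph <- whole_molecule_descriptors(test_molecules()$phenol)
  expect_equal(unname(ph["n_hbd"]), 1)
  expect_equal(unname(ph["n_hba"]), 1)
  expect_equal(unname(ph["mol_weight"]), 94.113, tolerance = 1e-3)

  # volume is additive: dropping one hydrogen removes 4/3 pi R_H^3
  tol <- whole_molecule_descriptors(test_molecules()$toluene)
  benzv <- unname(benz["topological_volume"])
  # toluene = benzene - H + CH3: volume difference is one C + two extra H
  props <- element_properties()
  expect_equal(unname(tol["topological_volume"]) - benzv,
               4 / 3 * pi * (props["C", "radius"]^3 + 2 * props["H", "radius"]^3),
               tolerance = 1e-10)
})

test_that("Z-score normalization uses training statistics only", {
  X <- matrix(c(1, 3, 10, 20), 2, 2,
              dimnames = list(NULL, c("topological_volume", "cheb_0_0")))
  attr(X, "kinds") <- c("whole_molecule", "qna_chebyshev")
  params <- fit_normalization(X)
  Xn <- apply_normalization(X, params)
  expect_equal(unname(Xn[, "topological_volume"]), c(-1, 1)) # population sd
  expect_equal(unname(Xn[, "cheb_0_0"]), c(10, 20)) # untouched
  expect_lt(abs(mean(Xn[, "topological_volume"])), 1e-12)
  # a shifted test point keeps the training mean/sd
  xt <- c(topological_volume = 5, cheb_0_0 = 0)
  tn <- apply_normalization(xt, params)
  expect_equal(unname(tn[, "topological_volume"]), (5 - 2) / 1)
  # schema error
  bad <- matrix(1, 1, 1, dimnames = list(NULL, "other"))
  attr(bad, "kinds") <- "whole_molecule"
  expect_error(apply_normalization(bad, params), "schema")
})
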