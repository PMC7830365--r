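# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# cached synthetic dataset (74 compounds, noise-free, fixed seed)
syn74 <- function() {
  if (is.null(fixture_env$syn74)) {
    fixture_env$syn74 <- synthetic_antioxidant_dataset(74, noise_sd = 0,
                                                       seed = 1)
  }
  fixture_env$syn74
}

# small molecule set reused across descriptor tests
test_molecules <- function() {
  if (is.null(fixture_env$mols)) {
    fixture_env$mols <- list(
      water = read_smiles("O", "water"),
      methane = read_smiles("C", "methane"),
      ethane = read_smiles("CC", "ethane"),
      benzene = read_smiles("c1ccccc1", "benzene"),
      phenol = read_smiles("c1ccccc1O", "phenol"),
      toluene = read_smiles("Cc1ccccc1", "toluene"),
      aniline = read_smiles("Nc1ccccc1", "aniline"),
      uracil = read_smiles("O=C1C=CNC(=O)N1", "uracil"),
      nitrophenol = read_smiles("Oc1ccc(cc1)[N+](=O)[O-]", "nitrophenol")
    )
  }
  fixture_env$mols
}

# a small pool of valid random-ish SMILES for property tests
random_smiles_pool <- function() {
  c("C", "CC", "CCC", "CCO", "CC(C)O", "CC(=O)O", "c1ccccc1", "Cc1ccccc1",
    "Oc1ccccc1", "Nc1ccccc1", "Clc1ccccc1", "c1ccc2ccccc2c1", "CCN", "CCS",
    "CC(C)(C)C", "COC", "C=C", "C#N", "CC#N", "OCC(O)CO", "c1ccncc1",
    "O=C1C=CNC(=O)N1", "CC(=O)Nc1ccccc1", "Oc1ccc(O)cc1", "FC(F)(F)c1ccccc1")
}

# brute-force matrix exponential: scaled Taylor series to machine precision
expm_taylor <- function(M, tol = 1e-16) {
  k <- max(0, ceiling(log2(max(1, norm(M, "1")))))
  A <- M / 2^k
  E <- diag(nrow(M))
  term <- diag(nrow(M))
  j <- 1
  repeat {
    term <- term %*% A / j
    E <- E + term
    if (max(abs(term)) < tol) break
    j <- j + 1
    if (j > 200) break
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# naive-loop reference implementation of the external-validation metrics
naive_metrics <- function(y, yh, tm) {
  n <- length(y)
  rss <- 0; sae <- 0
  for (i in seq_len(n)) {
    rss <- rss + (y[i] - yh[i])^2
    sae <- sae + abs(y[i] - yh[i])
  }
  my <- sum(y) / n; myh <- sum(yh) / n
  sxy <- 0; sx2 <- 0; sy2 <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - my) * (yh[i] - myh)
    sx2 <- sx2 + (y[i] - my)^2
    sy2 <- sy2 + (yh[i] - myh)^2
  }
  r2 <- (sxy / sqrt(sx2 * sy2))^2
  k <- sum(y * yh) / sum(y^2)
  r2_0 <- 1 - sum((yh - k * y)^2) / sum((yh - myh)^2)
  kp <- sum(y * yh) / sum(yh^2)
  r2_0p <- 1 - sum((y - kp * yh)^2) / sum((y - my)^2)
  q2f1 <- 1 - rss / sum((y - tm)^2)
  q2f2 <- 1 - rss / sum((y - my)^2)
  ccc <- 2 * (sxy / n) / (sx2 / n + sy2 / n + (my - myh)^2)
  abs_err <- abs(y - yh)
  list(r2 = r2, r2_0 = r2_0, r2_0_prime = r2_0p, q2_f1 = q2f1, q2_f2 = q2f2,
       rm2 = r2 * (1 - sqrt(abs(r2 - r2_0))),
       rm2_prime = r2 * (1 - sqrt(abs(r2 - r2_0p))),
       ccc = ccc, rmsep = sqrt(rss / n), mae = sae / n, sd = sd(abs_err))
}
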