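#' Substituent rule table
#'
#' SMILES fragments that can be grafted onto the family scaffolds,
#' together with their electronic effect on the chain-termination
#' activity. `donor_strength` is the additive lgk7 increment of one
#' occurrence: positive for electron donors (raising activity) and
#' negative for acceptors (lowering it). On the uracil family the
#' hydroxyl and amino groups act against the usual donor trend and carry
#' the `uracil_strength` values instead.
#'
#' @return data.frame with columns `name`, `fragment`, `donor_strength`,
#'   `uracil_strength`.
#' @export
substituent_rules <- function() {
  data.frame(
    name = c("CH3", "tBu", "OCH3", "OH", "NH2", "Cl", "COOH", "NO2"),
    fragment = c("C", "C(C)(C)C", "OC", "O", "N", "Cl", "C(=O)O",
                 "[N+](=O)[O-]"),
    donor_strength = c(0.40, 0.50, 0.80, 0.90, 1.10, -0.45, -0.90, -1.60),
    uracil_strength = c(0.40, 0.50, 0.80, -0.50, -0.40, -0.45, -0.90, -1.60),
    stringsAsFactors = FALSE
  )
}

# baseline lgk7 of the unsubstituted family scaffolds
family_base_lgk7 <- c(phenol = 3.6, aminophenol = 5.3,
                      aromatic_amine = 4.3, uracil = 1.4)

# number of substitutable positions per family scaffold
family_positions <- c(phenol = 5, aminophenol = 4, aromatic_amine = 5,
                      uracil = 4)

# assemble a SMILES for a family scaffold with substituents at positions;
# subs: named character vector position -> fragment SMILES ("" = H)
scaffold_smiles <- function(family, subs = character(0)) {
  frag <- function(p) if (p %in% names(subs)) subs[[p]] else ""
  br <- function(p) { f <- frag(p); if (nzchar(f)) paste0("(", f, ")") else "" }
  switch(family,
    phenol = paste0("Oc1c", br("1"), "c", br("2"), "c", br("3"),
                    "c", br("4"), "c1", frag("5")),
    aromatic_amine = paste0("Nc1c", br("1"), "c", br("2"), "c", br("3"),
                            "c", br("4"), "c1", frag("5")),
    aminophenol = paste0("Oc1c", br("1"), "c", br("2"), "c(N)c", br("3"),
                         "c1", frag("4")),
    # pyrimidine-2,4-dione: positions 1/2 = N-substituents, 3/4 = C5/C6
    uracil = paste0("O=C1C", br("3"), "=C", br("4"), "N", br("2"),
                    "C(=O)N1", frag("1")),
    stop("unknown family: ", family)
  )
}

# additive ground-truth activity of one (family, substituent set)
true_lgk7 <- function(family, sub_names, rules = substituent_rules()) {
  base <- family_base_lgk7[[family]]
  col <- if (family == "uracil") "uracil_strength" else "donor_strength"
  eff <- if (length(sub_names) > 0) {
    sum(rules[match(sub_names, rules$name), col])
  } else 0
  base + eff
}

#' Generate synthetic antioxidant structures
#'
#' Assembles distinct substituted scaffolds from the requested families
#' (phenols, aminophenols, aromatic amines, uracils). The enumeration
#' starts with a designed core -- each unsubstituted scaffold plus its
#' strongest-donor and strongest-acceptor single-substituent variants and
#' two range anchors -- emulating how curated training sets deliberately
#' span the activity scale; the remaining structures are seeded random
#' draws of one to three substituents. Duplicates are rejected by
#' canonical-SMILES comparison.
#'
#' @param n Number of distinct structures (>= 1).
#' @param families Non-empty subset of `phenol`, `aminophenol`,
#'   `aromatic_amine`, `uracil`.
#' @param seed Integer seed; the same seed reproduces the same list.
#' @return List of `ao_molecule`, each carrying attributes `family`,
#'   `substituents` (character vector of rule names) and `smiles`.
#' @export
generate_molecules <- function(n, families = c("phenol", "aminophenol",
                                               "aromatic_amine", "uracil"),
                               seed = 1L) {
  stopifnot(n >= 1)
  families <- match.arg(families, several.ok = TRUE)
  rules <- substituent_rules()
  set.seed(seed)

  cands <- list() # each: list(family, subs (named fragment vec), sub_names)
  add_cand <- function(family, positions, sub_names) {
    subs <- stats::setNames(rules$fragment[match(sub_names, rules$name)],
                            as.character(positions))
    cands[[length(cands) + 1]] <<- list(family = family, subs = subs,
                                        sub_names = sub_names)
  }
  # designed core: unsubstituted + strongest donor/acceptor per family
  for (fam in families) {
    add_cand(fam, integer(0), character(0))
    add_cand(fam, 1, "NH2")
    add_cand(fam, 1, "NO2")
  }
  # range anchors pushing towards the ends of the activity scale
  if ("aminophenol" %in% families) add_cand("aminophenol", c(1, 2), c("NH2", "OCH3"))
  if ("uracil" %in% families) add_cand("uracil", c(3, 4), c("NO2", "NO2"))

  max_attempts <- min(max(200L, 60L * n), 25000L)
  attempts <- 0L
  seen <- character(0) # raw-SMILES pre-filter before canonical dedup
  while (length(cands) < 3L * n && attempts < max_attempts) {
    attempts <- attempts + 1L
    fam <- sample(families, 1)
    k <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    npos <- family_positions[[fam]]
    k <- min(k, npos)
    pos <- sample.int(npos, k)
    subs <- sample(rules$name, k, replace = TRUE)
    smi <- scaffold_smiles(fam, stats::setNames(
      rules$fragment[match(subs, rules$name)], as.character(pos)))
    if (smi %in% seen) next
    seen <- c(seen, smi)
    add_cand(fam, pos, subs)
  }

  smiles <- vapply(cands, function(cc) scaffold_smiles(cc$family, cc$subs),
                   character(1))
  canon <- canonical_smiles(smiles)
  keep <- !is.na(canon) & !duplicated(canon)
  cands <- cands[keep]
  smiles <- smiles[keep]
  if (length(cands) < n) {
    stop("cannot enumerate ", n, " distinct structures from families ",
         paste(families, collapse = ", "), "; maximum reached: ",
         length(cands))
  }
  cands <- cands[seq_len(n)]
  smiles <- smiles[seq_len(n)]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn_%03d", i)
    mol <- read_smiles(smiles[i], id)
    attr(mol, "family") <- cands[[i]]$family
    attr(mol, "substituents") <- cands[[i]]$sub_names
    out[[i]] <- mol
  }
  out
}

#' Attach structure-linked synthetic activities
#'
#' `lgk7 = base(family) + sum(substituent effects) + Normal(0, noise_sd)`,
#' clipped to the observed activity window [0.01, 6.65]. Electron-donor
#' substituents raise the activity and acceptors lower it; on uracils the
#' hydroxyl/amino groups carry negative increments. At zero noise adding
#' a donor substituent never lowers lgk7 (monotone by construction,
#' except where clipping saturates).
#'
#' @param mols Molecules from [generate_molecules()].
#' @param noise_sd Gaussian noise, lgk7 units (0 = deterministic).
#' @param seed Integer seed for the noise.
#' @return An `ao_dataset` carrying a `truth` attribute: the generating
#'   coefficients, the unclipped activities, `noise_sd` and `seed`.
#' @export
generate_activity <- function(mols, noise_sd = 0, seed = 1L) {
  if (length(mols) == 0) stop("empty molecule list")
  rules <- substituent_rules()
  raw <- vapply(mols, function(m) {
    fam <- attr(m, "family")
    if (is.null(fam)) stop("molecule '", m$id,
                           "' lacks generator metadata (family attribute)")
    true_lgk7(fam, attr(m, "substituents"), rules)
  }, numeric(1))
  set.seed(seed)
  eps <- stats::rnorm(length(mols), 0, noise_sd)
  lgk7 <- pmin(pmax(raw + eps, 0.01), 6.65)
  ds <- activity_dataset(vapply(mols, `[[`, "", "id"), mols, lgk7)
  attr(ds, "truth") <- list(base = family_base_lgk7, rules = rules,
                            raw_lgk7 = raw, noise_sd = noise_sd, seed = seed)
  ds
}

#' One-call synthetic activity dataset
#'
#' @param n Number of compounds (default 74).
#' @param noise_sd Activity noise in lgk7 units.
#' @param seed Integer seed (drives both enumeration and noise).
#' @param families Scaffold families to draw from.
#' @return An `ao_dataset` (see [generate_activity()]).
#' @export
synthetic_antioxidant_dataset <- function(n = 74L, noise_sd = 0, seed = 1L,
                                          families = c("phenol", "aminophenol",
                                                       "aromatic_amine",
                                                       "uracil")) {
  mols <- generate_molecules(n, families = families, seed = seed)
  generate_activity(mols, noise_sd = noise_sd, seed = seed + 1L)
}

#' Simulate an inhibited-oxidation experiment
#'
#' Inverts the steady-state relations of inhibited chain oxidation: the
#' inhibition parameter is `F = fk7 [InH] / sqrt(2 k6 Vi)`, the inhibited
#' rate V solves `V^2 + F V0 V - V0^2 = 0` (positive root, so V = V0 at
#' F = 0), and the induction period is `tau = f [InH] / Vi`.
#' Multiplicative Normal(1, noise_frac) noise is applied to the simulated
#' rates and induction periods.
#'
#' @param fk7 Effective chain-termination constant f*k7 (L mol^-1 s^-1).
#' @param f Stoichiometric inhibition coefficient.
#' @param v0 Uninhibited oxidation rate (mol L^-1 s^-1).
#' @param vi Initiation rate (mol L^-1 s^-1).
#' @param k6 Peroxyl recombination constant (L mol^-1 s^-1).
#' @param concs Inhibitor concentrations (mol L^-1); the default is five
#'   points spanning 0.2e-4 .. 1.61e-4.
#' @param noise_frac Relative noise level (0 = exact).
#' @param seed Integer seed.
#' @return An [inhibition_experiment()].
#' @export
generate_kinetics <- function(fk7, f, v0 = 5e-6, vi = 1e-7, k6 = 1.9e7,
                              concs = seq(0.2e-4, 1.61e-4, length.out = 5),
                              noise_frac = 0, seed = 1L) {
  stopifnot(fk7 > 0, f > 0, v0 > 0, vi > 0, k6 > 0, all(concs > 0))
  Fv <- fk7 * concs / sqrt(2 * k6 * vi)
  if (any(!is.finite(Fv)) || any(Fv > 1e12)) {
    stop("parameters produce an inhibition parameter too large to simulate")
  }
  v <- v0 * (-Fv + sqrt(Fv^2 + 4)) / 2
  tau <- f * concs / vi
  set.seed(seed)
  v <- v * stats::rnorm(length(v), 1, noise_frac)
  tau <- tau * stats::rnorm(length(tau), 1, noise_frac)
  v <- pmin(v, v0) # noise must not push an inhibited rate above v0
  inhibition_experiment(v0 = v0, vi = vi, k6 = k6,
                        points = data.frame(inh_conc = concs, v = v),
                        tau_points = data.frame(inh_conc = concs, tau = tau))
}
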