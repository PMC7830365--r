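# aoqsar

QSAR consensus modeling of antioxidant chain-termination rate constants,
plus the inhibited-oxidation kinetics analysis that measures them.

## What it is for

The reliable quantitative measure of antioxidant activity is k7, the
rate constant (L mol^-1 s^-1) for the reaction of an antioxidant with
the peroxyl radicals that relay liquid-phase chain oxidation. `aoqsar`
is for researchers who want to

* model lgk7 = log10(k7) from 2-D structure for substituted phenols,
  aminophenols, aromatic amines and uracils,
* validate such models with the full external-validation metric suite
  used in the QSAR literature, and
* extract fk7, the stoichiometric coefficient f and k7 from inhibited
  oxidation measurements (initial rates and induction periods).

## The methods at its core

**Descriptors.** Per-atom QNA values built from ionization potentials
and electron affinities, coupled through the matrix exponential of the
connectivity matrix — P = B∘(E·B), Q = B∘(E·(B∘A)) with E = exp(−C/2),
A_k = (IP_k+EA_k)/2, B_k = (IP_k−EA_k)^(−1/2) — and aggregated into
molecule features as means of 2-D Chebyshev products T_m(P′)·T_n(Q′);
MNA substructure descriptors (recursive atom-neighbourhood strings with
ring/acyclic marks) as squashed count vectors; and whole-molecule
descriptors (topological length, topological volume Σ 4/3 π R³,
additive lipophilicity, physicochemical counts) with training-set
Z-score normalization.

**Regression.** Self-consistent regression (SCR): regularized least
squares a = (XᵀX+V)⁻¹Xᵀy whose per-variable regularization v_k is
updated to σ̂²/a_k² and whose weak variables are dropped by t-ratio;
then RBF-SCR interpolation y(x) = Σ w_i φ(‖a∘x − a∘x_i‖) with the
linear kernel φ(r) = r, every training point a center, w = Φ⁻y.

**Consensus.** 20 partial RBF-SCR models per descriptor type (320,
160 + 160, for combined models), each built on a bootstrap resample and
a random feature subset; the prediction is the partial mean and the
spread their standard deviation, with similarity / leverage / accuracy
applicability-domain flags.

**Validation.** Ranked k:1 train/test splits (74 compounds: 4:1 →
59/15, 5:1 → 62/12), 20-fold leave-many-out CV releasing 20% per fold,
metrics R², R²₀, R²₀′, Q²F1, Q²F2, rm² (avg and Δ), CCC, RMSEP, MAE,
S.D., and a four-condition high/moderate/low predictivity grading.

**Kinetics.** F = V₀/V − V/V₀ = f·k₇[InH]/√(2k₆Vᵢ) fitted on initial
rates; τ = f[InH]/Vᵢ fitted through the origin; k₇ = fk₇/f.

A synthetic-data module generates structure-linked activity datasets
(additive substituent effects, clipped to lgk7 ∈ [0.01, 6.65]) and
simulated kinetic experiments, so the whole pipeline is exercisable
without any external data.

## Worked example

```r
library(aoqsar)

ds <- synthetic_antioxidant_dataset(74, noise_sd = 0, seed = 1)
ds
#> <ao_dataset> 74 compounds, lgk7 0.01..6.65 (mean 3.82, sd 2.12, delta 6.64)

sp <- rank_and_split(ds, 4)          # ranked 4:1 split: 59 train / 15 test
model <- build_consensus(sp$train, "mna", seed = 1)
model
#> <ao_consensus> mna, 20 partials, 59 training compounds, RMSE(train) = 0.442

pred <- predict_consensus(model, sp$test$molecules)
report <- compute_metrics(sp$test$lgk7, pred$lgk7_pred, mean(sp$train$lgk7))
report
#> <validation report> n=15  R2=0.910  R2_0=0.639  Q2F1=0.825  Q2F2=0.824
#>   rm2(avg)=0.541  drm2=0.209  CCC=0.883  RMSEP=0.882  MAE=0.685  SD=0.575

classify_predictivity(report, diff(range(sp$train$lgk7)))
#> <predictivity> grade: moderate  (unmet high conditions: determination_coefficients, rm2, mae, mae_plus_3sd )
```

The test-set R² of 0.91 shows the ensemble recovers the generator's
structure–activity relationship on held-out compounds; the grade is
"moderate" because the strict four-condition "high" rule also demands
near-unit through-origin coefficients and an MAE below 10% of the
6.6-log-unit training range.

Kinetics of a simulated inhibition experiment (five inhibitor
concentrations spanning (0.2–1.61)·10⁻⁴ mol/L):

```r
ex <- generate_kinetics(fk7 = 4.8e5, f = 2)
fit_inhibition(ex)
#> <inhibition fit> fk7 = 4.8e+05  f = 2  k7 = 2.4e+05  lgk7 = 5.38  (R2 = 1.0000)
```

fk₇ is read off the slope of F vs [InH] (times √(2k₆Vᵢ)), f from the
through-origin slope of τ vs [InH] (times Vᵢ), and k₇ = fk₇/f — here
2.4·10⁵ L mol⁻¹ s⁻¹, i.e. lgk₇ = 5.38.

File-level commands (`ao_featurize_file`, `ao_train`, `ao_predict_file`,
`ao_kinetics_file`) and the `inst/scripts/aoqsar` wrapper run the same
pipeline from SMILES/SDF/CSV on disk.

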