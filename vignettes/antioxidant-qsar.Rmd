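---
title: "Modeling antioxidant chain-termination rate constants with aoqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antioxidant chain-termination rate constants with aoqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoqsar)
```

## The modeling problem

In liquid-phase chain oxidation of hydrocarbons, an antioxidant InH
terminates oxidation chains by reacting with peroxyl radicals; the rate
constant of that reaction, k7 (L mol^-1 s^-1), is the quantitative
measure of antioxidant activity. Experimental k7 values for substituted
phenols, aminophenols, aromatic amines and uracils span more than six
orders of magnitude (lgk7 roughly 0.01 to 6.65), with electron-donating
ring substituents raising the activity and electron-withdrawing ones
lowering it. `aoqsar` implements a complete QSAR pipeline for modeling
lgk7 from 2-D structure: atomic descriptors of two families (QNA and
MNA), whole-molecule descriptors, consensus ensembles of
self-consistent-regression/radial-basis-function models, external
validation, applicability-domain diagnostics, and the inhibited-oxidation
kinetics analysis that produces experimental k7 values in the first
place.

## Molecular representation

Structures enter as SMILES or SDF (V2000) and are normalized to a
hydrogen-complete chemical graph: every hydrogen explicit, element
labels, formal charges, per-atom ring and aromaticity flags, and a 0/1
connectivity matrix `C`. Bond orders are deliberately not retained --
neither descriptor family consumes them. Parsing, hydrogen saturation,
canonicalization and ring perception are delegated to OpenBabel
(via ChemmineOB/ChemmineR). Multi-fragment inputs (salts, mixtures) are
rejected rather than desalted, since the modeled chemical series are
single molecules. Stereochemistry, tautomers and 3-D geometry are out of
scope for the same reason.

Element constants are shipped as a plain CSV
(`inst/extdata/element_properties.csv`): first ionization potential IP
and electron affinity EA (eV), van der Waals radius (Angstrom), atomic
mass, an additive lipophilicity increment, and hydrogen-bond donor /
acceptor flags for H, C, N, O, F, S, Cl, Br and I. Users can swap the
whole table via `element_properties(path)`. Because published IP/EA
compilations differ in their third decimals, absolute QNA values depend
mildly on the table choice; all relationships the package tests are
invariant to that choice as long as IP > EA for every element (enforced
at load time).

## QNA descriptors and Chebyshev features

Each atom k carries `A_k = (IP_k + EA_k)/2` and
`B_k = (IP_k - EA_k)^(-1/2)`. The per-atom values

```
P = B * (E B),   Q = B * (E (B A)),   E = exp(-C/2)
```

(elementwise products with `B`) describe each atom while depending on
the whole molecular topology through `E`.

A genuinely open design point is whether `exp(-C/2)` is a matrix
exponential or an elementwise one. We use the **matrix exponential**
(computed by `Matrix::expm`, verified in the tests against a
scaled-Taylor-series oracle at 1e-12): it propagates influence along
bond paths with weights decaying in bond distance, which is what makes P
and Q functions of the molecule as a whole. An elementwise exponential
of a 0/1 matrix would reduce P to a nearly size-only measure (each atom
would receive `e^(-1/2)` from bonded neighbours and exactly 1 from every
non-neighbour, swamping topology with atom count). The elementwise
variant remains available for comparison via
`ao_config(qna_exponential = "elementwise")`.

The regression layer consumes molecule-level features: means over atoms
of the two-dimensional Chebyshev products `T_m(P') T_n(Q')` for all
total degrees `m + n <= 4` (15 features, `cheb_m_n`). P and Q are
unbounded, so they are first squashed into (-1, 1) by
`x -> (2/pi) atan(x/s)`; the scale `s` is the median |P| (and |Q|) over
all atoms of the training set, frozen at fit time. The arctan squash is
smooth and monotone and the median scale is robust to outlying atoms;
both the polynomial degree and the squash scale are configuration keys
because no published account of the original implementation fixes them.
Since |T_k| <= 1 on [-1, 1] and averaging preserves bounds, every
feature lies in [-1, 1] by construction -- the common scale claimed for
these descriptors, asserted property-style in the tests.

## MNA descriptors

The level-0 MNA descriptor of an atom is its mark -- the element symbol,
prefixed with "-" when the atom is not in a ring. The level-k descriptor
is the notation `A(D1 D2 ...)` over the immediate neighbours' level-(k-1)
descriptors, concatenated in lexicographic order so that the string is a
canonical invariant of the atom environment (two arbitrary relabelings
of the same structure yield identical descriptor multisets; tested). We
generate levels 0..2 by default -- first and second neighbourhoods --
via `ao_config(mna_level = )`.

The original pipeline feeds MNA descriptors through a pretrained
biological-activity predictor and regresses on predicted activity
spectra. That trained base is proprietary and unavailable, so this
package regresses on the MNA count vectors directly: the vocabulary is
the lexicographic union of descriptors over the training set, and counts
x are squashed onto [-1, 1) by `u = x/(1+x)`, `feature = 2u - 1` (absent
descriptor -> -1), honouring the descriptor scale without needing a
training-set maximum. This substitution is the one deliberate departure
from the original pipeline; everything downstream (ensemble
architecture, validation, kinetics) is unaffected by it.

## Whole-molecule descriptors and normalization

Three molecule descriptors -- topological length (maximal inter-atomic
bond-count distance), topological volume (sum of atomic volumes
`4/3 pi R^3`), and an additive atom-contribution lipophilicity
(approximate by design; the increments ship with the element table) --
plus physicochemical counts: positive/negative formal charges,
hydrogen-bond donors (N/O bearing hydrogen) and acceptors (N/O/F),
aromatic atoms, molecular weight and halogen count. Only this block is
Z-score normalized (training mean and population standard deviation,
frozen in the featurizer); the QNA-Chebyshev and MNA features already
live on [-1, 1] and pass through unchanged. Zero-variance training
features are flagged and dropped from modeling.

## Self-consistent regression and RBF interpolation

SCR is regularized least squares, `a = (X'X + V)^(-1) X'y` with
`V = diag(v_k)` and an unpenalized intercept. The published account
gives this solution but not the self-consistency rule, so the package
uses a standard automatic-relevance scheme, documented as its own
choice: after each solve, `v_k <- sigma^2 / a_k^2` (current residual
variance over the squared coefficient), so weak variables acquire large
penalties and shrink further; variables with t-ratio
`|a_k|/se(a_k) < 2` are dropped; the loop runs to stability or 50
iterations (both configurable). Two limiting behaviours anchor the
implementation and are asserted in the tests: `v = 0` reproduces OLS to
1e-8, and a fixed common `v = lambda` reproduces ridge regression's
closed form. As noise vanishes the scheme recovers generating
coefficients to 1e-6.

RBF-SCR then interpolates: every training point is a center, coordinates
are weighted by the SCR coefficients (zero weight for dropped
variables), and with the linear kernel `phi(r) = r` the model is
`y(x) = sum_i w_i ||a*x - a*x_i||` with `w` solving `Phi w = y`. `Phi`
is inverted by a rank-revealing pseudo-inverse, so duplicated centers
(as bootstrap resamples produce) degrade gracefully to the least-squares
solution instead of failing. Training points are reproduced exactly
whenever the weighted centers are distinct -- the odd linear kernel
makes the distance matrix of distinct points generically nonsingular.

## Consensus ensembles

A single-descriptor-type consensus holds exactly 20 partial regressions;
a combined model holds 320 (160 on QNA features, 160 on MNA features).
The partials are "built independently of each other"; the published
account does not say how they differ, so the package induces diversity
by per-partial randomization: a bootstrap resample of the training
compounds and a random 50% subset of the type-specific features, with
the three whole-molecule descriptors and physicochemical counts always
added as candidates. Child seeds derive deterministically from the
master seed: the same seed rebuilds a byte-identical serialized
ensemble. The consensus prediction is the plain arithmetic mean over
partials and the reported spread is their standard deviation (population
form, n denominator, so two partials predicting 1.0 and 3.0 give spread
1.0). An optional flag drops partials with negative internal training
R2; it is off by default, keeping plain averaging.

## Applicability domain

Three conventions, each a configuration key because the defining
reference formulas are not public:

* **similarity** -- mean Euclidean distance to the 3 nearest training
  vectors, compared against the training set's own 95th percentile of
  the same leave-self-out statistic;
* **leverage** -- hat value `h = 1/n + (x - c)'(Xc'Xc)^-(x - c)` against
  the usual `3p/n` cutoff (p = effective rank + 1; the training centroid
  has h = 1/n and is always in);
* **accuracy** -- mean absolute out-of-bag residual of the 3 nearest
  training compounds (each partial predicts the compounds its bootstrap
  missed) against twice the training RMSE.

A prediction is in-domain when all three hold. On small training sets
the accuracy check is deliberately conservative: out-of-bag residuals
estimate holdout error, which can exceed twice the resubstitution RMSE.

## Train/test splitting, cross-validation and validation metrics

`rank_and_split()` ranks compounds by increasing lgk7 (stable sort) and
transfers evenly spaced ranked positions to the test set; the test size
is `n/(k+1)` rounded half-up -- the only rounding consistent with both
reference set sizes (74 compounds: 4:1 gives 59/15, 5:1 gives 62/12).
`cross_validate_lmo()` performs 20 independent seeded random splits each
releasing 20% of the compounds, rebuilding the model every time, and
pools the held-out predictions.

`compute_metrics()` reports R2; the through-origin determination
coefficients R2_0 (predicted on observed) and R2_0' (observed on
predicted); Q2F1 (denominator around the training mean) and Q2F2
(around the test mean); rm2 = R2(1 - sqrt(|R2 - R2_0|)), its primed
counterpart, their average and absolute difference; Lin's concordance
correlation coefficient; RMSEP; MAE; and S.D. computed as the n-1
standard deviation of the absolute errors (pairing it with MAE in the
threshold sums below). A systematic-error flag fires when the mean
signed residual exceeds `2 RMSEP / sqrt(n)`. The whole suite is checked
against an independent naive-loop implementation at 1e-10.

`classify_predictivity()` applies four conditions for the **high** grade:
all six determination coefficients at least 0.85 with pairwise spread at
most 0.1 (our operationalization of "close to each other and tending to
unity"; both knobs exposed), rm2 average > 0.5 with difference < 0.2,
MAE at most 10% of the training activity range, and MAE + 3 S.D. at most
20% of it. The mirrored **low** conditions use the 0.6 ceiling, 15% and
25%; anything else is **moderate**.

## Inhibited-oxidation kinetics

For an initiated, inhibited oxidation at steady state the inhibition
parameter `F = V0/V - V/V0` is linear in inhibitor concentration,
`F = f k7 [InH] / sqrt(2 k6 Vi)`, and the induction period is
`tau = f [InH] / Vi`. `fit_fk7()` regresses F on [InH] (the intercept is
kept as a linearity diagnostic and a sub-0.95 R2 warns), converting the
slope with user-supplied k6 and Vi, which the package logs rather than
assumes; `fit_f()` fits tau through the origin (the relation has no
intercept) and multiplies the slope by Vi; `compute_k7()` forms
k7 = fk7/f. The simulator inverts these relations exactly -- V is the
positive root of `V^2 + F V0 V - V0^2 = 0`, so V = V0 at F = 0 -- and a
noise-free simulate-then-fit round trip recovers any positive (fk7, f)
to better than 0.1%, which the acceptance checks exercise at the
reference values fk7 = 4.8e5 L mol^-1 s^-1 and f = 2. The default
experiment constants (`v0` = 5e-6, `vi` = 1e-7 mol L^-1 s^-1,
`k6` = 1.9e7 L mol^-1 s^-1) are typical of AIBN-initiated ethylbenzene
oxidation near 348 K and sit in the configuration, as does the default
five-point concentration grid spanning (0.2-1.61)e-4 mol L^-1.

## The synthetic-data generator

Experimental compound tables with curated k7 values are not
redistributable, so the package generates structure-linked surrogates:
substituted phenols, aminophenols, aromatic amines and uracils assembled
by grafting common substituents (CH3, t-Bu, OCH3, OH, NH2, Cl, COOH,
NO2) onto the family scaffolds. The activity model is additive --
`lgk7 = base(family) + sum(substituent increments) + noise` -- clipped
to the observed window [0.01, 6.65]. Donors carry positive increments
and acceptors negative ones; on uracils the hydroxyl and amino groups
carry negative increments, encoding the observation that their effect
on that family runs against the usual donor trend. Enumeration starts
with a designed core (each unsubstituted scaffold, its strongest-donor
and strongest-acceptor variants, and two range anchors) before seeded
random draws, emulating how curated training sets deliberately span the
activity scale; this construction guarantees an activity range above 6
log units for any set of 30+ compounds, the working requirement for a
reliable training set.

What passing tests on this generator do and do not show: the synthetic
activity is exactly additive in substructure counts, so it is learnable
in principle from MNA-type features, and pipeline-recovery results
(test R2 of about 0.9 on the noise-free 74-compound set under the 4:1
split) demonstrate that the machinery is wired correctly -- not that the
descriptors would achieve that accuracy on laboratory k7 data, where
electronic effects are neither additive nor local and measurements carry
error. Clipping at the window boundaries also breaks additivity there by
design.

## Numerical choices and problem sizes

Matrix exponentials are computed to machine precision; the SCR loop
declares convergence at a 1e-10 relative coefficient change; RBF weight
systems and leverage matrices use SVD pseudo-inverses with the standard
rank tolerance; models serialize to JSON with 17 significant digits so a
round trip is byte-identical. The test suite and the acceptance script
run the full pipeline at the reference scale (74 compounds, 59-compound
training sets, 20- and 320-member ensembles) and use 12-40-compound
subsets for unit-level checks; these sizes keep the whole suite at a few
minutes on one CPU.

## Known limitations

* MNA count features replace the original activity-spectrum layer (see
  above); absolute model statistics are therefore not comparable with
  the original implementation, only the architecture and contracts are.
* The applicability-domain formulas are stated conventions, not the
  original (unpublished) rules.
* The lipophilicity increment scheme is an order-of-magnitude additive
  model, not a fitted logP predictor.
* Aromaticity affects only the aromatic-atom count; MNA marks encode
  ring membership, not aromaticity.
* The kinetics module implements the steady-state relations only; it
  does not integrate the underlying radical mechanism.
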