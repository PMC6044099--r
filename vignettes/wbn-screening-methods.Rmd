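---
title: "Methods: weighted Burden number virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted Burden number virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wbnscreen)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic benchmarks do and do not
demonstrate.

## 1. The screening problem

Confirmatory high-throughput bioassays are extremely imbalanced: on the
order of a thousand confirmed actives against several hundred thousand
inactives. Training a classifier directly on such data is both
computationally heavy and statistically fragile, and a model built on a
couple of hundred correlated descriptors is hard to interpret. The package
therefore implements a workflow of six stages — descriptor generation,
validated down-sampling, PCA-based descriptor prioritization, ensemble
("panel") screening, self-organizing-map similarity, and structural-alert
triage — each usable on its own.

## 2. Molecule model and annotation

Molecules are hydrogen-suppressed graphs. SMILES and SDF input is
interpreted by OpenBabel (via ChemmineOB) and converted internally through
the MOL2 representation, which keeps aromatic atoms and bonds, Sybyl atom
types, formal charges and explicit hydrogens; hydrogens are folded into
per-heavy-atom counts. For multi-fragment records the largest connected
fragment is kept (salt stripping beyond that is out of scope). Bond orders
are 1, 2, 3, with aromatic bonds carried as 1.5.

Three per-atom properties feed the descriptors:

* **Electronegativity (EN).** Pauling values per element, shipped as a
  versioned YAML table (`inst/extdata/atom_properties.yaml`); unknown
  elements fall back to 2.0 with a logged message.
* **Gasteiger charge (GC).** Computed in-package by the classic iterative
  partial equalization of orbital electronegativities (PEOE):
  χ(q) = a + bq + cq², parameters keyed on Sybyl atom types, transfers
  damped by 2^-k per iteration, hydrogen cation electronegativity fixed at
  20.02. Implicit hydrogens participate as pseudo-atoms and their converged
  charges are folded back into the bonded heavy atom, so the per-molecule
  charge sum equals the total formal charge to machine precision (the unit
  suite checks 1e-3; the implementation conserves exactly). A unit test
  cross-checks the values against OpenBabel's independent Gasteiger
  implementation at a loose 0.1 tolerance — the two parameterizations
  differ in detail, particularly for conjugated heteroatoms.
* **Lipophilicity (LP).** A simplified Wildman–Crippen-style table of
  atomic logP increments keyed on Sybyl types, hydrogens absorbed into the
  heavy-atom value. The table is deliberately coarse and versioned so a
  finer scheme can be swapped in; numerical identity with any particular
  logP program is a non-goal.

Pharmacophore classes (donor, acceptor, positive, negative, hydrophobic,
aromatic) are assigned by explicit atom-typing rules over element, type,
charge, aromaticity and hydrogen count rather than by SMARTS data files:
the classes depend on implicit-hydrogen counts that live in the graph
model, and keeping the rules as code makes them testable atom by atom.
Amide and pyrrole-type nitrogens are excluded from acceptors; carboxylate
oxygens count as negative regardless of which oxygen formally carries the
charge.

## 3. Weighted Burden numbers

The Burden connectivity matrix places an atomic property on the diagonal
and small bond-derived constants off the diagonal:

* diagonal: EN, GC or LP value of the atom;
* bonded pair: `w · b(order)` with b = 0.1 (single), 0.2 (double), 0.3
  (triple), 0.15 (aromatic), plus 0.01 if either atom is terminal;
* non-bonded pair: 0.001.

The weight fraction w takes the four values 0.25, 0.50, 0.75, 1.00 — the
raw weights 2.5, 5.0, 7.5 and 10.0 divided by ten, so descriptor names
carry the conventional "0.50/0.75/1.00" suffixes. The highest (H) and
lowest (L) eigenvalues of the twelve matrices give 24 descriptors. The
off-diagonal base values follow Burden's original formulation; the raw
weights only fix the scaling, so the 0.01 terminal correction and the
0.001 non-bonded constant are documented here and locked by tests against
a brute-force dense oracle, Gershgorin disc bounds and atom-permutation
invariance.

The 8-property block (MW, summed-increment logP, a coarse N/O-contribution
TPSA, donor and acceptor counts, rotatable bonds, aromatic ring count,
heavy atoms) and the 147-bit pharmacophore-pair fingerprint (21 unordered
class pairs × 7 shortest-path bins: 2, 3, 4, 5, 6, 7, ≥8 bonds) complete
the 179-column schema. The fingerprint block reproduces the *size* and
*shape* of the classic pharmacophore fingerprint block, not any specific
program's bit semantics — that fidelity is a declared non-goal, and
nothing downstream depends on it.

## 4. Sampling and Z-test validation

`split_mix_sample()` splits the inactives into k (default 15) contiguous
near-equal chunks, pools each chunk with **all** actives, and draws a
simple random sample of `round(f·N)` (round-half-up, f default 0.05)
without replacement, with a per-set RNG stream derived from the master
seed. `ztest_validate()` then compares each sampled set to the population:

z = (x̄ − μ) / (σ/√n), two-sided p = 2(1 − Φ(|z|)),

with μ and σ taken from the full population table (a one-sample test with
known σ — the population is available, so nothing needs estimating). A set
*passes* when all monitored descriptors (default: the WBN block) have
p ≥ α = 0.05. Independently of the pass flags, the `exclude_n` (default 1)
sets with the lowest aggregate monitored means are flagged for exclusion —
passing and exclusion are deliberately distinct mechanisms, mirroring the
practice of dropping the set with the lowest descriptor values even when
every set passes.

Two statistical notes. First, sampling 5% without replacement makes the
test slightly conservative (finite-population correction ≈ 0.95 on the
variance); the property suite checks the empirical per-test rejection rate
against α under a null generator where labels are independent of the
descriptors. Second, with ~14 sets × ≥3 monitored descriptors the event
"every test passes simultaneously" has low probability under uniform
p-values — per-test calibration, not the joint all-pass event, is the
meaningful property, and that is what the suite asserts. Mixing all
actives into every pool also means that when descriptors genuinely carry
the activity signal, sampled-set means are *expected* to drift from
population means; with realistic (<1%) prevalence the drift is small, but
it is the reason pass flags are reported rather than used to drop sets.

## 5. PCA prioritization

`pca_descriptors()` standardizes the in-scope columns and
eigen-decomposes the correlation matrix (not covariance — descriptor
scales differ by orders of magnitude). Scope defaults to the continuous
block (WBN + properties): z-scoring near-constant binary bits is
ill-behaved, and the prioritized subset of interest consists of WBN
descriptors. Per-variable contributions to a component are squared
unit-norm loadings (they sum to one); signs follow the convention that
each component's largest-magnitude loading is positive. `select_pcad()`
keeps the m (default 14) variables contributing most to the first
component F1; contributions tied to 1e-12 (duplicated columns) resolve by
schema order. A multi-component criterion (eigenvalue-weighted sum over
leading components) exists behind the `components` argument but is
non-default — the first component alone is the documented criterion.

Where several training sets exist, the pipeline runs PCA on the first
retained set. Pooling all sets is a defensible alternative (the sets are
exchangeable samples of one population), but a single-set default keeps
the stage's input explicit and reproducible; the choice is configurable by
passing any table to `pca_descriptors()`.

One caveat worth stating: F1 of a descriptor table is typically a
molecular *size/polarity* factor. On synthetic libraries the selection
therefore recovers the dominant variance direction, which coincides with
the planted activity-bearing descriptors only when they dominate F1 (as in
the planted-structure generator). This unsupervised character is inherent
to the method, not an implementation artifact.

The 14-name reference selection ships in
`inst/extdata/pcad_reference.txt` as a fixture; `pcad_reference()` loads
it.

## 6. Panel screening

`crossval_metrics()` runs stratified 10-fold cross-validation, pools
out-of-fold hard predictions (probability cutoff 0.5) into one confusion
matrix, and derives TP rate, TN rate, accuracy, precision, F-measure,
Cohen's kappa, MCC and a rank-statistic (Mann–Whitney) AUC in-house. Ratios
with undefined denominators — including kappa and MCC for degenerate
predictions — are 0 by a documented convention. The formulas are locked by
enumeration over every confusion matrix with n ≤ 20 against independent
oracles (`cor()` for MCC, `e1071::classAgreement` for kappa).

Learners are a pluggable `fit`/`predict_prob` contract. The default wraps
`randomForest`: 100 trees, √p feature subsampling per split, and a
class-balanced bootstrap (equal per-class `sampsize`), a standard choice
for imbalanced bioassays. `train_panel()` fits one member per training
set; single-class sets are skipped with a warning. `panel_screen()` counts
hard votes and selects compounds with at least t votes — default t = 10
regardless of ensemble size, the "selected by 10 or more training sets"
consensus rule, with `threshold = "fractional"` (⌈0.71·E⌉) for other
ensemble sizes. Votes are hard per-member predictions, not averaged
probabilities, to match the per-set "selected by" semantics.

## 7. Self-organizing map

`som_fit()` implements the standard online Kohonen update on a
rectangular grid (default 5×5): weights initialized by sampling input
rows, Gaussian neighborhood, exponential decay of learning rate (α₀ = 0.5
over `epochs` = 100) and radius (σ₀ = half the grid). Inputs are
standardized with training-population statistics so screened compounds and
reference drugs share one space. Best-matching units break ties toward the
lower row-major index; `co_location_report()` lists, for each reference
compound, the non-reference compounds sharing its cell. Including known
drugs among the mapped rows is sometimes described as "supervised" use of
a SOM; the update here is the standard unsupervised one and reference
compounds are ordinary rows flagged for reporting — a documented
divergence. Quantization-error decay, cluster separation and seeded
determinism are property-tested.

## 8. Structural alerts

Rules are YAML entries (name, SMARTS, kind, points). `reject` rules
eliminate on any match; `demerit` rules accumulate points once per rule
(no per-match multiplicity) and a compound is rejected when the total
*exceeds* the threshold (default 100, the published convention).
Matching is OpenBabel SMARTS. The shipped demo set covers a dozen
reactive/promiscuity motifs (quinone, Michael acceptor, aldehyde,
nitroaromatic, epoxide, hydrazine, thiol, perfluoroalkyl chain, ...); the
engine accepts arbitrary user rule files, and reproducing any full
published rule set is out of scope.

## 9. Synthetic data

`generate_library()` assembles structures from a fragment grammar —
starters, divalent linkers, extendable units and monovalent caps chosen so
every concatenation is valence-legal — which guarantees parseable, valid
chemistry with realistic descriptor variance (rings, heteroatoms, charged
groups, and motifs the alert rules can hit). Activity is drawn
Bernoulli(sigmoid(β₀ + β·z(d(x)) + ε)) where d(x) are designated WBN
descriptors computed on the generated structure (defaults: five WBN
descriptors with β = (2, 1.5, 1.5, 1, 1), logit noise sd 0.5),
and β₀ is calibrated by bisection to the target prevalence. The default
prevalence is 0.05: at desk scale a sub-1% prevalence would leave sampled
training sets of a dozen rows with no actives, and 5% matches the active
fraction of the *mixed per-set pools* that the sampling stage actually
trains on (roughly a thousand actives against ~19,000 inactives per
chunk). `generate_table()` is the cheaper tabular analogue: planted
columns share a latent factor (loading 5, noise sd 1 by default), labels
follow a logistic model on the factor.

What passing synthetic tests shows: the machinery — schema, sampling
arithmetic, test calibration, recovery of planted low-rank structure,
ensemble voting, map clustering, alert logic — behaves as specified. What
it does not show: performance on real bioassay chemistry, where descriptor
distributions are heavier-tailed, activity is not a clean function of five
descriptors, and class imbalance is far more severe.

## 10. Numerical choices and problem sizes

* Eigenvalues via LAPACK's symmetric solver; descriptor reproducibility is
  asserted to 1e-9 under atom permutation, and CSV round-trips to 12
  significant digits.
* PEOE: 20 damped iterations max, convergence at 1e-8 on the largest
  transfer.
* Seeds: every stochastic stage derives a stream as
  `derive_seed(master, index)` (an affine hash folded below 2^31), so
  stages are independently reproducible and re-runs are byte-identical.
* Round-half-up for sample sizes (R's `round()` is banker's rounding).
* The test suites run at deliberately modest sizes — libraries of 150–250
  molecules for property suites, 100 seeds of n = 500 tables for the
  recovery rate, 20 seeds of n = 250 libraries for the paired
  cross-validation comparison, and one n = 2000 end-to-end screen — sizes
  chosen to exercise every code path and statistical claim while keeping a
  full check fast on a laptop.

## 11. Known limitations

* Descriptors are purely topological; no 3D, conformers, tautomers or
  protonation states.
* The lipophilicity and TPSA tables are coarse stand-ins; swap the YAML
  for higher fidelity.
* PEOE parameters cover the common organic elements (C, N, O, S, P,
  halogens); exotic atoms fall back with a logged message.
* PCA prioritization is unsupervised: it finds dominant variance, not
  activity relevance, and the two coincide only when activity-bearing
  descriptors dominate the first component.
* With very small sampled training sets (a dozen rows), random-forest
  members are weak and panel precision gains over baseline are modest —
  the consensus rule, not individual model quality, carries the screen at
  desk scale.
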