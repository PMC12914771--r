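---
title: "Methods: sort-seq enrichment, ensemble regression, and selective inhibitor design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq enrichment, ensemble regression, and selective inhibitor design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsdesign)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the judgement calls made where the underlying methodology
leaves room.

## The problem

Homologous enzymes — here the catalytic domains of matrix
metalloproteinases MMP-1, MMP-3 and MMP-9, which share ~45% sequence
identity and nearly identical folds — are hard to inhibit selectively.
A natural broad-spectrum inhibitor (the N-terminal domain of TIMP-2) can
be re-specialised by mutating a few binding-interface positions, but the
combinatorial space over seven positions (20^7 ≈ 1.3 × 10^9 sequences) is
far beyond what affinity selections can screen. The package's strategy:
measure a *sample* of that space by sorted-library deep mutational
scanning against each enzyme, train a regression model per enzyme, and
then search the *whole* space in silico for variants predicted to bind
the intended target strongly and the off-targets weakly.

## From reads to labels

A variant is its **signature**: the residues at the targeted positions in
ascending position order (`"SINSVHT"` is the wild type of the default
scheme). Reads are filtered before counting: shorter than the reference
(`TOO_SHORT`), carrying a non-canonical residue (`INVALID_RESIDUE`), or
mutated at a *non-targeted* position (`OFF_TARGET_MUTATION`) — the last
because an off-target substitution changes binding in a way the signature
cannot represent, which would corrupt the labels. Rejections are tallied,
and accepted plus rejected always equals input reads.

Per gate, frequencies are `f = n / total`; dividing by the wild-type
frequency gives the normalised frequency `NF`, and the enrichment ratio is
`ER = NF(gate) / NF(presort)`, with `log2 ER` as the model label. Two
useful consequences, both under test: scaling every count by a constant
leaves all ERs unchanged, and swapping the gate and presort roles negates
every `log2 ER`.

**Zero counts.** The ratio is undefined for variants absent from either
fraction. The default *excludes* such variants (tallying them as
`NOT_IN_PRESORT` / `NOT_IN_GATE`), matching the presence-based variant
inventories that sorted-library experiments report. An optional
`pseudocount` shifts every count in the union of both tables instead, for
robustness analyses; it is off by default because it biases labels of
well-sampled variants for the benefit of barely-sampled ones. A related
open choice — whether a minimum read threshold beyond presence should
apply — is left at presence (count ≥ 1), the least-assuming reading of the
protocol.

## The affinity model

Signatures are one-hot encoded position-major (20 × 7 = 140 binary
inputs). Two small multilayer perceptrons are supported, named after their
original use on library-scale and alanine-scan data: `Lib` (32 then 4
rectified units, 20%/10% dropout) and `Ala` (8 then 2 units, 0%/30%
dropout), each ending in one linear output. Their trainable parameter
counts, 4,649 and 1,149, are asserted in the tests as a shape check.

Choices the methodology leaves open, fixed here as follows:

* **Loss**: weighted mean-squared error; per-example weights multiply the
  squared errors inside each minibatch mean.
* **Optimiser**: Adam at the grid's learning rate, no weight decay, no
  early stopping — epochs are a hyper-parameter, so training runs exactly
  as long as configured.
* **Determinism**: initialisation (He-scaled gaussians), epoch shuffling
  and dropout masks all derive from the member seed, so a member is
  bit-reproducible given (data, hyper-parameters, seed). The ensemble is
  10 members at seeds `base_seed + 0..9`, and its prediction is their
  mean with dropout disabled.
* **Split**: examples are ranked by total read count (presort + gate);
  the deepest 10% are the test set, the next 10% validation. Read depth
  is a proxy for label reliability, so evaluation happens on the
  most trustworthy labels. Ties break lexicographically on the signature,
  making the split fully deterministic; the split is computed once and
  reused across the whole grid, and the test fold is scored exactly once.
* **Sample weighting**: `log2(count_presort + count_gate)`. A variant seen
  once in total gets weight 0 — no training influence — which is accepted
  behaviour: under presence-in-both-gates filtering such variants cannot
  occur anyway (minimum raw weight is 2).

**Grid size.** The declared search ranges (6 batch sizes × 5 epoch counts
× 6 learning rates × 2 architectures × 2 weighting modes) multiply to 720
combinations, although the methodology is usually quoted as a 360-point
search; the discrepancy is documented rather than resolved — `hp_grid()`
generates the full product and accepts restrictions of any axis, so either
convention is reproducible.

**Correlation.** Model selection and evaluation use the plain
product-moment Pearson correlation, implemented directly and checked
against a naive two-pass oracle to 1e-12; constant vectors raise
`ZERO_VARIANCE` rather than returning `NaN`.

## The design stage

Selectivity needs multiple simultaneous mutations, so candidates are drawn
from the **fully mutated** space: every targeted position non-WT, 19^7 ≈
8.9 × 10^8 signatures for the default scheme. That space is streamed in
batches — the residues at two chosen positions are fixed per batch (19^2
batches of 19^5) — while a running top-k by predicted `log2 ER` is kept;
the result is provably independent of which positions are batched on, and
the tests check batched enumeration against brute force on reduced
schemes. Desk-scale runs can instead rank a seeded uniform sample of the
fully mutated space (`mode = "sampled"`).

Each candidate is then profiled against off-target models by its
**selectivity percentile**: the percentage of the *entire* variant space
(20^7, WT letters included) predicted to bind the off-target more
strongly. Strictly-greater comparison is used, so ties count in the
candidate's favour; the default is Monte-Carlo estimation with 10^6 draws
plus a binomial standard error, with exhaustive mode available for reduced
schemes. No automatic final pick is made — the report ranks candidates
and leaves the choice, which in practice weighs off-target percentiles
against each other, to the scientist.

**Sign convention.** Models trained on a *low*-affinity gate assign
strong binders *negative* `log2 ER` (strong binders are depleted from a
low gate). Rather than hard-coding an affinity direction, ranking
functions accept `decreasing = FALSE`; correlations are reported signed.
Notably, low-gate models are the better design tool in this framework:
a high-stringency gate saturates for strong binders (a variant cannot be
more than maximally present), whereas depletion from the low gate keeps
discriminating among ever-stronger binders. The end-to-end recovery test
and the acceptance script therefore design on the low-gate model.

## Tight-binding kinetics

When inhibitor and enzyme concentrations are comparable, free-inhibitor
depletion cannot be neglected and the classical IC50 analysis fails;
Morrison's quadratic expression for the fractional residual velocity is
the standard treatment. The implementation clamps the discriminant at
zero (floating-point cancellation near stoichiometric equivalence) and
clips the result to [0, 1]; it reduces to `Kiapp/(Kiapp + I)` as E → 0,
which is under test.

`fit_ki()` treats `Kiapp` as the sole free parameter per replicate
("global fit" across a replicate's concentration series), optionally
co-fitting a velocity scale when raw rather than normalised rates are
supplied (the scale is profiled out linearly, keeping the search
one-dimensional). The optimisation is a deterministic golden-section
search on log10(Kiapp) over 1e-5..1e7 nM — no starting guess, no
stochasticity. Replicates are fit independently and summarised as mean ±
sample SD, matching how triplicate kinetics experiments are reported.
Degenerate inputs fail loudly: fewer than four distinct concentrations is
under-determined, and uniformly uninhibited curves raise `NO_SIGNAL`.

Units: concentrations are nM internally; the substrate concentration S
and Michaelis constant Km (µM) enter only as the ratio S/Km in
`Kiapp = Ki (1 + S/Km)`. The packaged assay constants are E = 0.325 nM,
S = 7.5 µM, and Km = 3.607 / 3.771 / 4.75 µM for MMP-1/-3/-9.
Pre-incubation equilibration is assumed, not modelled. Fold changes are
displayed rounded to the nearest integer at ≥ 10 and to two significant
digits below, the convention of published selectivity tables, with raw
ratios retained. Independent model validation (`ki_er_validation()`)
normalises each variant's Ki by the wild-type Ki of the same study before
correlating `log2(Ki/Ki_WT)` with predicted `log2 ER`, which removes
inter-study scale differences.

One library-bookkeeping convention worth flagging:
`theoretical_variant_count()` reproduces the customary library-design
denominators (140 singles, 8.4 × 10^3 doubles, ... over 7 positions),
which allow *any* of the 20 letters at each chosen position and therefore
double-count lower-order variants. The strict partition uses 19 non-WT
letters per position, and the identity
`sum_k C(7,k) 19^k = 20^7` is asserted numerically in the tests.

## The synthetic world

The generator exists so that every stage has a testable surface with
known truth. Its defaults were chosen once, to mirror the scale of a real
single-mutant-centred saturation mutagenesis experiment, and are not
tuning knobs:

* **Landscape**: additive per-(position, residue) energies, i.i.d.
  normal with SD 1 and WT pinned at 0; optional sparse pairwise epistasis
  (SD 0.5). Energy stands in for true binding affinity.
* **Library**: 5,000 variant draws; mutation numbers drawn with weights
  131 : 3142 : 1526 : 81 : 1 for 1..5 mutations — the observed composition
  of such a library, dominated by doubles and triples; lognormal
  abundance skew (sdlog 1); WT pinned at 5% of the library, reflecting the
  strong WT background of a single-mutant-centred library and
  guaranteeing a well-covered normaliser.
* **Sorting**: two complementary gates; P(high gate) is logistic in
  energy with midpoint 0 (WT splits 50/50, centring its ER at 1) and
  steepness 1, i.e. commensurate with single-effect sizes.
* **Depth**: 10^6 reads per gate, multinomial, so a median variant gets
  ~10^2 reads — deep enough that label noise, not sampling pathology,
  dominates.
* **Reads**: optional off-target substitution and truncation rates
  exercise the dataset filters; read headers carry the truth for test
  introspection.

What a green end-to-end test establishes: with this depth and an additive
landscape, the pipeline's enrichment math, depth split, ensemble training
and design search jointly recover the planted truth (held-out Pearson vs
true log2 ER ≥ 0.8; the top designed candidate lands in the top 1% of
true target energy). What it does not establish: robustness to
sequencing-error models, PCR amplification bias, codon-level mutagenesis
statistics, strong epistasis, or gate mis-sorting — none of which the
generator emulates — nor, of course, performance on any real dataset.

## Known limitations

* The MLP is trained mostly on 1–3-mutation variants and extrapolates to
  the fully mutated space; rectifier networks extrapolate roughly
  linearly, which suits near-additive landscapes but will underestimate
  strong epistasis.
* High-gate labels saturate for strong binders (see the sign-convention
  note); design on high-gate models ranks the top of the space weakly.
* Exhaustive 19^7/20^7 scans are supported by the batched stream but are
  cluster-scale work in R; the desk default is seeded Monte-Carlo, whose
  percentile error (binomial SE) is reported alongside each estimate.
* `fit_ki` assumes equilibrated, competitive, tight-binding inhibition;
  slow-binding kinetics and active-site titration are out of scope, and
  Km is a supplied constant, not estimated.
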