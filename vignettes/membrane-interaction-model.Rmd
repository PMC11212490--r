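---
title: "The membrane-interaction model behind memsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The membrane-interaction model behind memsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsense)
```

# The problem

Peripheral membrane proteins adhere transiently to bilayer surfaces, and
many of them do so in a curvature-dependent way: amphipathic stretches
insert into the lipid packing defects that open up on curved or stretched
membranes. memsense predicts, from amino-acid sequence alone, a peptide's
*relative curvature-sensing free energy* ΔΔF — the difference in binding
affinity for a curved/stretched membrane versus a flat one, in kJ/mol,
more negative meaning stronger sensing — and converts it into
curvature-dependent binding probabilities and a three-way activity call:
**non-binder**, **curvature sensor**, or **membrane binder**. A second
module maps these calls onto protein 3D structures.

# The physics layer

Four relations connect the raw per-sequence prediction to an
interpretable binding probability. All constants live in a single
validated object, `pmi_constants()`, and can be overridden there or via a
`key = value` file (`read_constants_file()`).

**Length extrapolation.** ΔΔF scales linearly with peptide length L, so a
window of length L is extrapolated to the 24-residue reference:
ΔΔF_L24 = (a_L·24 + b_L)/(a_L·L + b_L) · ΔΔF, with a_L = −1.03 and
b_L = 3.28. The factor is 1 at L = 24 and ≈ 5.46 at L = 7, which is why
short-peptide predictions (≤ 12 residues) carry a caution: the
extrapolation amplifies both signal and error.

**Charge adjustment.** Most biomembranes are negatively charged while the
reference membrane is neutral; each unit of positive peptide charge adds
c_z = −0.93 kJ/mol: ΔΔF_adj = ΔΔF_L24 + c_z·z. It is applied only when
the user selects an anionic target membrane. The calibration range is
z ∈ [−1, +4]; outside it the package emits a caution rather than refusing.

**Binding free energy.** The absolute binding free energy to a vesicle of
radius R (nm) is an affine map plus a strain-scaled curvature term:
ΔF_sm(R) = α·ΔΔF_eff + β + (ΔΔF_eff/ε_ref)·(1/R² + 2/R), with α = 3.83,
β = 12.27 kJ/mol, and ε_ref = 0.165 the relative strain of the reference
stretched membrane. A flat membrane is passed as `radius = Inf`, for which
the strain term is exactly zero.

**Binding probability.** P_m = 1 / (1 + (N_s/N_m)·exp(ΔF_sm/RT)) with
N_s/N_m = 5.2·10³ the solvent/membrane state-count ratio and
RT = 2.478 kJ/mol (298.15 K). The exponent is clamped at ±700 before
exponentiation so extreme inputs saturate to 0/1 without overflow.

Two representation choices deserve a note, because the typeset form of
these equations admits more than one reading. The curvature term divides
by ε_ref (free energy per unit strain, scaled by the vesicle strain), and
the sigmoid exponent divides by RT. Both choices are pinned by an internal
consistency requirement rather than taste: with them, root-finding the
ΔΔF_eff values at which P_m(R = 50 nm) crosses 0.05 and 0.95
(`derive_class_boundaries()`) lands on −6.42 and −10.01 kJ/mol — exactly
the published classification thresholds of −6.4 and −10.0 at one-decimal
rounding. With either alternative reading, the crossings land elsewhere.
The temperature itself is not printed anywhere; 298.15 K is adopted and
documented (300 K reproduces the thresholds at one-decimal rounding too,
so nothing downstream hinges on the choice).

Classification uses the thresholds as printed, with the sensor interval
closed on both ends: non-binder above −6.4, sensor in [−10.0, −6.4],
binder below −10.0; ties therefore classify as sensor. No rounding is
applied before thresholding.

# The sequence regressor

The sequence → ΔΔF map is a small pre-LN multi-head self-attention
encoder (token + positional embeddings, 2 encoder layers, 4 heads, 32-dim
embeddings, position-wise feed-forward blocks, mean pooling over non-pad
positions, linear head), trained with Adam on mean-squared error. The
forward and backward passes are written out explicitly in base R matrix
algebra and gradient-checked against central finite differences in the
test suite. Everything — initialization, the 80/10/10 split, shuffling —
derives from `model_config()$seed`, so training is bit-reproducible.
Sequences shorter than 24 residues are right-padded; padding tokens are
masked out of both attention and pooling.

Alongside it stands an intentionally simple **additive baseline**
(`fit_additive_baseline()`): least squares of ΔΔF on residue counts. On
residue-additive data it is statistically optimal, which makes it the
independent oracle the encoder is judged against — the encoder must stay
within striking distance of the baseline, and both must approach the
noise floor.

# The synthetic-data generator

Training and evaluation run on synthetic data that emulate the salient
features of the coarse-grained MD peptide dataset the method is built
around: fixed-length 24-residue sequences with targets spanning the whole
applicability domain from inactive (0 kJ/mol) down to the theoretical
optimum near −30 kJ/mol, with ≈ 1 kJ/mol observation noise (comparable to
replica spread in MD free-energy estimates).

The generative model is additive: ΔΔF = Σᵢ c(aaᵢ) + N(0, σ), with
coefficients anchored at −0.55 × the Fauchère–Pliška hydrophobicity value
plus a small per-dataset jitter (±0.15 kJ/mol, drawn once per dataset).
The anchoring makes hydrophobic and bulky residues (W, F, I, L) carry
strongly negative contributions — the optimal sensor is hydrophobic and
bulky — while charged/polar residues contribute near zero or positively.
Uniformly random sequences would cluster near −6 kJ/mol, so sequence
composition is tilted per sequence by a Boltzmann weight exp(b·h) on the
hydrophobicity scale, with b drawn uniformly from (−0.75, 2.5); this
spreads the targets across the full domain, mimicking a dataset produced
by an optimization run rather than by uniform sampling.

What the generator deliberately does **not** emulate: positional or
pairwise epistasis (real ΔΔF is not exactly additive), the discrete
composition structure of evolved sequences, and any secondary-structure
signal. Passing the recovery and RMSE tests therefore shows that the
training machinery works and that the encoder can extract an additive
signal at the noise floor — it does not certify accuracy on real MD data,
for which the published external dataset can be dropped in via
`read_peptide_dataset()`.

Reduced-scale study sizes used throughout the tests: n = 5000 examples,
noise 1.0 kJ/mol, 8 training epochs for the headline RMSE bound
(held-out RMSE ≤ 2.0 kJ/mol, i.e. twice the noise floor; the trained
model typically reaches ≈ 1.05), and n in the hundreds for exact-recovery
checks.

# Structure screening

The screening pipeline (`annotate_structure()`, `run_screen()`) follows
five steps:

1. **Chain extraction.** One-letter sequences per chain from the polymer
   residues, in author numbering. Chains are split into fragments at
   numbering gaps and at unmappable residues; common modified residues
   (MSE, SEP, PTR, …) are mapped to their parents. Each fragment is
   screened independently.
2. **Sliding windows.** All L − w + 1 windows (default w = 15, a typical
   secondary-structure element). Fragments shorter than the window but at
   least 7 residues are scored as a single segment; shorter fragments are
   skipped with a warning (the predictor's 7-residue minimum).
3. **Window scoring.** Each window's prediction is length-extrapolated to
   the 24-residue reference, and — when the target membrane is anionic —
   charge-adjusted using the *window's own* net charge (side-chain rule:
   K, R = +1; D, E = −1; H and termini 0). The per-window choice (rather
   than whole-protein charge) matches the local character of the
   interaction being modelled. Residue n then receives the unweighted mean
   over all covering windows; terminal residues are covered by fewer
   windows and are correspondingly less precise.
4. **Exposure.** Per-residue SASA by the Shrake–Rupley algorithm
   (quasi-uniform Fibonacci lattice, 960 points/atom, 1.4 Å probe, Bondi
   radii; hydrogens ignored, waters dropped, other hetero atoms kept as
   occluders since they genuinely bury surface), summed per residue in
   nm², then smoothed over the 9-residue vicinity n−4..n+4 (truncated at
   fragment ends). The 0.8 nm² exposure threshold is applied to the
   *smoothed* value — smoothing is what turns a per-side-chain area into
   a property of the local stretch. SASA is computed on the full assembly;
   screening is per chain.
5. **Classification and output.** Thresholding always acts on the
   extrapolated/adjusted scale, never the raw window score. Residues
   below the exposure threshold keep their free energy but are labelled
   "not accessible". The annotated PDB encodes the call in the B-factor
   column: 0.0 (non-binder or inaccessible), 0.5 (sensor), 1.0 (binder);
   all other columns of a PDB input are preserved byte-for-byte.

# Benchmarking

`benchmark_screen()` implements a segment-based binary comparison against
user-supplied reference regions: each chain is cut into consecutive
15-residue fragments (trailing remainder dropped), a fragment is
predicted-positive when it contains at least `min_hits` residues labelled
sensor or binder (sensors count as hits by default; switchable), and
agreement is summarized as MCC, FDR and FOR. The `min_hits = 1` default
resolves the boundary case of exactly one hit as positive; the stricter
≥ 2 reading is available via the parameter. Degenerate denominators
yield 0 with an explicit flag rather than NaN.

# Numerical and degenerate-input choices

* Root-finding for the class boundaries brackets on [−80, 40] kJ/mol and
  uses Brent's method at 1e-10 tolerance.
* The sigmoid exponent clamp (±700) keeps `exp()` finite; probabilities
  saturate rather than overflow.
* A residue absent from all training sequences makes the baseline design
  rank-deficient; its coefficient is flagged `NA` (with a warning), not
  silently zeroed, and treated as 0 at prediction time.
* Non-finite training loss aborts with the epoch named.
* Fragments shorter than 7 residues, empty structures, misaligned
  benchmark inputs, and out-of-range windows (valid: 7–24) all fail with
  stage-specific messages.

# Known limitations

* The physics constants were fitted on coarse-grained MD of neutral
  POPC-type membranes; lipid-specific interactions are outside the model.
* An α-helical fold is implicitly assumed; non-helical peptides and
  domains deserve caution.
* Protein–protein interfaces expose hydrophobic surface and can be
  false-positive membrane regions.
* The shipped training pipeline is validated on synthetic additive data
  only; published performance on the external MD dataset is an optional
  experiment, not a packaged result.
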