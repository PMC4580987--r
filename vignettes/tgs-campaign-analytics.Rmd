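---
title: "Models and methods behind tgskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tgskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgskit)
```

`tgskit` re-implements, as reusable and tested components, the analysis
chain of a kinetic target-guided synthesis (TGS) campaign against a
protein target and the downstream profiling of its hits. This vignette
is the package's own account of the underlying models, the parameters
that matter, and the choices made where the design was genuinely open.

## 1. Exact-mass product enumeration

The screen's readout is mass: an in-situ formed triazole is recognized
in an LC–MS feature table by the exact mass of its azide + alkyne sum
formula. Atom conservation of the Huisgen cycloaddition means the
product formula is the element-wise sum of the reagent formulas, and
the 1,4- and 1,5-regioisomers are isobaric — they can only be told
apart chromatographically.

Masses are computed from a hardcoded monoisotopic isotope table
(H, C, N, O, F, S, Cl, Br, Na, P, I) at 6-decimal precision, which
bounds the table-induced error below 1 µDa per atom — two orders of
magnitude below the ~1 mDa scale that a 5 ppm window at m/z 200–600
corresponds to. Only singly charged adducts ([M+H]⁺, [M+Na]⁺, [M−H]⁻)
are supported: time-of-flight analysis of <600 Da products does not
produce multiply charged species in practice. Formulas are taken as
supplied; there is no valence or structure perception (deliberately —
reagent structures are campaign metadata, not something a mass pipeline
should re-derive).

The shipped 2-azide × 90-alkyne table is synthetic: real campaign
structures live in supplementary materials of their publications, so
the package generates a plausible, clearly labeled stand-in with the
same shape and SAR vocabulary (naphthyl vs phenyl warheads;
amide/sulfonamide/ether/alkyl linkers; cycloalkyl, phenyl, heteroaryl,
alkyl head groups).

## 2. Orthogonal pooling and intersection deconvolution

Items are laid row-major on an R × C grid; partition X pools are the
rows, partition Y pools the columns. On a full grid every |X_i ∩ Y_j| = 1,
so one hit row plus one hit column identifies a single item — the
9 × 10 case gives nine X pools of 10, ten Y pools of 9, and 90
singleton intersections. `verify_orthogonality()` checks this
exhaustively rather than trusting the construction, and reports
`valid = FALSE` (never an exception) for defective designs, because
design verification is a QC step users run on files they did not build.

Ragged grids (n < R·C) are allowed with empty cells; orthogonality then
degrades gracefully to "max pairwise overlap ≤ 1". Placement can be
permuted reproducibly (`shuffle`, `seed`) since real campaigns
randomize cluster composition.

## 3. The campaign simulator

The simulator stands in for the wet-lab instrument chain and ships a
recoverable ground truth, which is what makes end-to-end testing of the
deconvolution logic possible.

Kinetics are abstracted to a **two-level amount model**: every pair
present in an incubation forms its triazole at background level
`k_bg`; in the enzyme condition, pairs in the planted binder set are
boosted by `templation_factor`. This is deliberate — no rate constants
are available for the templated cycloaddition, only the qualitative
observation that templating accelerates 1,4- and 1,5-isomer formation
to comparable extents, so the boost applies to both regioisomers of a
binder pair. An optional `competition` mode fixes the *total* templated
excess per mixture at `k_bg × (templation_factor − 1)` and splits it
equally among binder products present, modeling a shared enzyme budget.

Noise model and defaults (chosen once, as typical TOF-LC-MS behaviour):

| parameter | default | rationale |
|---|---|---|
| `k_bg` | 100 a.u. | arbitrary intensity unit anchor |
| `templation_factor` | 20 | a templated product must clear the LOD decisively; 20× is the qualitative "present vs absent" contrast the readout relies on |
| `lod` | 250 a.u. | between background (100) and templated (2000): background is usually invisible, as in the real campaign where buffer controls are mostly clean |
| `ppm_sigma` | 2 ppm | typical TOF mass accuracy |
| `intensity_cv` | 0.3 | typical LC-MS peak-intensity CV; lognormal (multiplicative, strictly positive) |
| `rt_jitter` | 0.05 min | run-to-run RT stability of a short gradient |
| `enzyme_conc`, `reagent_conc` | 4.8 µM, 0.1 mM | carried as metadata only; they do not enter the amount model (published concentration bookkeeping is internally inconsistent at the protocol level, which is harmless here precisely because amounts are abstracted) |

Retention times are drawn once per product from U(1, 20) min;
regioisomers get distinct RTs (they co-mass but separate on the
column). A fixed `seed` makes the entire simulation byte-reproducible.

What the simulator does **not** emulate: chromatographic peak shapes,
isotope envelopes, adduct heterogeneity, ion suppression in mixtures,
and any inhibition of the enzyme by formed products. Passing tests
therefore demonstrate the correctness of the *pipeline logic* under a
realistic error budget, not instrument-level fidelity.

## 4. Matching, hit calling, deconvolution

Feature matching restricts candidates to the products of the reagents
actually present in that incubation — mixture composition is known by
design, and this restriction is what prevents cross-pool false
assignment. Within the candidates, assignment goes to the smallest
|ppm error| within `ppm_tol` (default 5 ppm). Exact regioisomer mass
ties are resolved by nearest retention time within `rt_tol` when a
reference RT library exists, otherwise kept regio-ambiguous; ambiguous
hits count toward deconvolution as the pair, since regiochemistry is
only ever settled against synthesized standards. Mass ties between
*different* pairs are broken deterministically (higher library index)
and flagged.

Hit calling pairs each enzyme incubation with its buffer control and
requires enzyme intensity ≥ LOD and enzyme/buffer ratio ≥ 3 (ratio is
∞ when the buffer lacks the product; `threshold = Inf` gives strict
presence/absence calling). Products seen only in buffer are never hits.

Deconvolution confirms a pair in `intersection` mode only when it is
hit in both its X-pool and its Y-pool context for the same azide —
the conservative reading of a two-partition campaign — with `either`
mode available for treating partitions as independent discovery arms.
Precision/recall against a supplied ground truth are computed at the
pair level (regiochemistry collapsed, matching how the simulator
plants binders).

Under the default noise budget (2 ppm, CV 0.3), the dominant loss
mechanism is a binder feature drifting outside the 5 ppm window in one
pool context; with two regioisomers × two contexts per pair, recovery
stays essentially complete, which the acceptance checks quantify over
100 seeded campaigns.

## 5. Dose–response potency

Percent inhibition anchors raw signals between vehicle (0 %) and a
full-inhibition reference (100 %). Curves are fitted with the standard
increasing four-parameter logistic

y = A + B / (1 + (C/x)^D),

A = minimum, B = range, C = IC50, D = slope factor, by bounded
Levenberg–Marquardt least squares on log10(C) (log-parameterization
makes the optimizer scale-free in concentration; the fit is invariant
to unit rescaling). Starting values A = min(y), B = range(y),
C = geometric-mean concentration, D = 1; bounds A ∈ [−20, 50],
B ∈ [0, 200], D ∈ [0.3, 5] — robust settings for percent-inhibition
data. A curve whose top response never reaches 50 % at the highest
tested concentration is *censored* (`IC50 > c_max`), carries no finite
C, and is excluded from downstream regression — the only interpretable
treatment of "> limit" potencies.

Ki follows Cheng–Prusoff, Ki = IC50/(1 + [S]/Km), with the assay
settings [S]/Km = 0.35 (Aβ-derived peptide substrate) and 0.29
(insulin); at these ratios Ki and IC50 rank compounds nearly
identically, which is why cross-substrate agreement can be assessed on
pIC50 directly. The cross-substrate regression is ordinary least
squares (nothing in the source assays justifies an errors-in-variables
model, though the orthogonal variant is a one-line change); published
per-compound IC50 tables are supplementary-only, so the regression
constants are validated by synthetic recovery, not literal
reproduction.

The simulation study behind the recovery claim uses 8-point half-log
curves whose IC50 is bracketed by at least one decade of tested
concentration on each side — an IC50 at the top tested concentration
is, by the censoring convention above, not a fittable curve — and 2 %
assay noise applied as a coefficient of variation, the way plate-assay
precision is conventionally quoted.

## 6. ADME and pharmacokinetics

One linear-trapezoid AUC implementation (`auc_trapezoid`) is shared by
every time-course summary. Non-compartmental analysis takes Cmax/tmax
by direct maximum; the terminal rate constant λ_z by log-linear OLS
over the candidate tails (last n ≥ 3 positive post-peak points)
choosing the window with maximal adjusted R² — published reports
rarely state a window rule, and this selection is exact on noiseless
exponentials regardless of window; AUC∞ = AUC(0→t) + C_last/λ_z. When
fewer than three positive post-peak points exist, extrapolated
quantities are reported absent rather than fabricated.

Microsomal stability uses the log-linear depletion slope
(t½ = 0.693/k, keeping the literal 0.693 where the field's formula
prints it) and CLint = dose/AUC∞ of the fitted exponential — which
collapses to k/protein_conc, reported in µl·min⁻¹·mg⁻¹ at the standard
0.6 mg/ml microsomal protein. Plasma stability fits one-phase
exponential decay by nonlinear least squares; a half-life beyond the
observation window is censored to "> window" (a fully flat profile
short-circuits to that result, since zero-decay data make the
exponential fit singular). Caco-2 permeability uses the standard
Papp = (dQ/dt)/(A·C₀) and recovery definitions with the 0.33 cm²
Transwell geometry and the conventional 1.0 × 10⁻⁶ cm/s high/low
classification threshold on A→B transport.

## 7. Two-state SAXS analysis

The conformational question — how much of a flexible enzyme is in its
open state, and does an inhibitor shift it closed — is answered by
expressing an observed scattering curve as a two-state mixture
s·[f·I_open(q) + (1−f)·I_closed(q)]. Because the model is linear in
(a, b) = (s·f, s·(1−f)), the σ-weighted least-squares problem is
solved in closed form from the 2 × 2 normal equations, with
non-negativity handled on the boundary; f = a/(a+b) is scale-invariant
by construction. Identical (or effectively identical) basis profiles
are flagged degenerate rather than producing an arbitrary f. Basis
profiles on foreign q grids are linearly interpolated onto the
observed grid; extrapolation is refused.

The package ships *analytic sphere* bases (I(0) = 1 normalized sphere
form factor; Rg = √(3/5)·R, Dmax = 2R) as stand-ins for
atomic-coordinate scattering calculations, which are out of scope.
Imported basis profiles from external calculators are read with the
standard 3-column `q I σ` text format. When simulated noise is
multiplicative at level c, its per-point uncertainty σ = c·I belongs
in the fit: weighting makes all q regions count in relative terms,
without which the near-identical low-q region of two similar
conformers dominates and the fraction is poorly identified.

**Guinier window choice.** Rg comes from OLS of ln I on q² with the
window found self-consistently (iterate until q_max·Rg ≤ `q_rg_max`).
The conventional globular-particle limit q·Rg ≤ 1.3 is the default,
but it is worth being explicit about its systematic error: for an
ideal sphere, ln I = −x²/5 − 0.002857·x⁴ + … (x = qR), and the
next-order term biases the fitted Rg *upward* by ~1.8 % at a window
ending at q·Rg = 1.3, ~1.1 % at 1.0, and ~0.9 % at 0.9 — this is a
property of the Guinier approximation itself, not of the estimator.
Closed-form recovery checks in the test suite therefore run at
`q_rg_max = 0.9`, inside the 1 %-accurate regime, while the behaviour
at the 1.3 default is separately regression-tested against its known
~2 % ceiling. For experimental (noisy) data the 1.3 default remains
the sensible bias/variance compromise.

Indirect Fourier transform machinery — P(r), regularized Dmax
estimation — is intentionally not implemented; Dmax is only available
in the analytic-sphere case (2R) for synthetic tests.

## 8. Problem sizes and numerical conventions

The shipped studies use: 100 noiseless plus 100 noisy simulated
campaigns (full 9 × 10 design, both partitions, 76 incubations each)
for deconvolution performance; 200 synthetic 8-point curves for IC50
recovery; a 1-min grid over 0–2000 min for the NCA closed-form check;
200 noisy mixtures for the SAXS fraction study. These sizes give
stable statistics while keeping the whole suite fast to re-run.

Conventions: natural log for all log-linear regressions; ties at equal
|ppm error| broken deterministically and flagged; degenerate inputs
(flat depletion, all-zero PK profiles, identical SAXS bases,
sub-50 %-top dose-response curves) produce flagged/censored results
rather than errors wherever the input is plausible field data, and
errors with named offenders wherever the input violates a contract
(unknown element symbols, duplicate reagent ids, missing buffer
partners, cluster labels absent from a design).

## 9. Known limitations

* The simulator's two-level kinetics cannot inform rate-based claims
  (e.g. time-course of templated formation); it is a detection model.
* Feature matching assumes centroided, deisotoped features; no
  isotope-pattern scoring.
* SAR summaries are descriptive fold enrichments without significance
  testing — at 90 alkynes the campaign is not powered for that.
* The 4PL machinery targets percent-inhibition data; other response
  scales need user-supplied bounds.
* Sphere/ellipsoid bases capture size and gross shape only; claims
  about real two-state fractions require externally computed atomic
  basis profiles.
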