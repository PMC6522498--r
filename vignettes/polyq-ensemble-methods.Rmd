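---
title: "Chemical-shift propensity and ensemble reweighting for polyQ flanking helices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-shift propensity and ensemble reweighting for polyQ flanking helices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqens)
```

## The problem

Polyglutamine (polyQ) proteins such as ataxin-7 are intrinsically
disordered in their monomeric form, yet their aggregation behaviour is
steered by transient, marginally stable secondary structure. In the
ataxin-7 N-terminal fragment an alanine-rich region (ARR, with its
C-terminal ARR2 motif) immediately precedes the tract; the ARR nucleates
a local α-helix that can propagate into the first glutamines, and tract
expansion raises the helical population of the tract itself. Because no
single rigid structure exists, the evidence is statistical: small
deviations of backbone chemical shifts from random-coil values,
ensembles of conformers reweighted to match those shifts, and backbone
amides whose hydrogen/deuterium exchange (HDX) is slowed by transient
hydrogen bonding. `polyqens` implements that analysis chain end to end,
together with a seeded generator of synthetic data with the same
statistical structure, so every stage can be exercised and validated
offline.

## Secondary shifts and the SSP score

For a nucleus $j$ of residue $i$ the secondary shift is
$\Delta\delta_{ij} = \delta^{\text{obs}}_{ij} - \delta^{\text{rc}}_{ij}$,
where $\delta^{\text{rc}}$ is the random-coil reference for that residue
type. The package bundles a Wishart-style random-coil table (documented
in the table's `provenance` attribute) for H, N, Hα, Cα and Cβ; a
configuration switch adds a −1.9 ppm Cα correction for residues followed
by proline. The per-residue difference
$\Delta\delta_{C\alpha} - \Delta\delta_{C\beta}$ is reported alongside:
sustained values above ~1 ppm indicate helical population.

The secondary-structure-propensity (SSP) score maps each observation
onto a common scale by normalising with the average secondary shift of
fully formed structure: an observation pointing in the helix direction
is divided by the fully-formed-helix offset for its nucleus, one
pointing the other way by the fully-formed-strand offset (and negated).
A fully formed helix therefore scores +1 and a fully formed strand −1
by construction, whatever reference offsets are bundled. Scores are
averaged over a sliding window (default 5 residues, odd) with
per-nucleus sensitivity weights (Cα and Cβ 1.0, Hα 0.8, amide H and N
0.3 — carbon shifts dominate helix/strand discrimination in disordered
proteins), and observations deviating from the window consensus by more
than one standard deviation are excluded as outliers before the final
weighted mean. A score is reported only where at least three window
residues contribute at least one usable nucleus, so chain termini are
truncated, and glycine (no Cβ) and proline (no amide) still receive
scores from their remaining nuclei. Both the window, the weights, the
outlier cutoff and the reference offsets are arguments, since published
SSP analyses differ in which nuclei they trust.

Two consequences worth knowing: the score is linear in the amplitude of
the secondary shifts (half-strength shifts score ≈ 0.5), and segment
calling (`call_segments()`) simply reports maximal runs of ≥ 3 residues
at or above a threshold, the same summary used to describe the ARR2
motif (scores > 0.3) and the early tract (> 0.15).

## Conformer model and forward shift model

Pool members are backbone conformations described by (φ, ψ) per residue.
`build_chain()` realises them as N/Cα/C/O coordinates with fixed ideal
geometry (N–Cα 1.46 Å, Cα–C 1.52 Å, C–N 1.33 Å, trans peptide bonds);
`assign_ss()` assigns three states from dihedral basins — helical
φ ∈ [−100, −30], ψ ∈ [−80, 0] sustained for ≥ 3 consecutive residues,
extended φ ∈ [−180, −90], ψ ∈ [90, 180] for ≥ 2, all else coil. This is
a declared simplification of hydrogen-bond-based assignment: 3₁₀/π-type
states map into H, and the basins are configurable. Terminal residues
lack one dihedral and are always coil.

The forward shift model is deliberately linear in the state:
$\delta^{\text{pred}}_{ij} = \delta^{\text{rc}}_{ij} +
\text{offset}_j(s_i)$ with offset 0 for coil and the fully-formed
helix/strand reference for H/E. Ensemble-averaged predictions are then
linear in the pool weights, which is the structural property the
reweighting step relies on (predictions from any trained external
predictor, once tabulated per conformer, have the same property; a
precomputed matrix can be imported via `read_shift_matrix_csv()`). The
model has no ring-current, neighbour or dihedral fine terms; its
accuracy is qualitative by design.

## Reweighting a conformer pool

Given the pool prediction matrix $M \in \mathbb{R}^{K \times J}$ and
experimental values $y$, `fit_weights()` solves

$$\min_{w \in \Delta^{K-1}} \; \sum_j \Big(\sum_k w_k M_{kj} - y_j\Big)^2
  + \lambda \lVert w \rVert^2$$

over the probability simplex. The objective is plain least squares on
ppm values (optional per-observable weights allow inverse-variance
scaling per nucleus); λ defaults to 0. Because the equality constraint
fixes $\sum_k w_k = 1$, subtracting any constant vector from all rows
and from $y$ leaves the objective unchanged; columns are therefore
mean-centred before solving, which removes the large common random-coil
component and conditions the Gram matrix. The resulting strictly convex
quadratic program is solved exactly with a dual active-set method
(`quadprog`), with an escalating ridge fallback only if the Gram matrix
is numerically semidefinite. The fit records the attained objective,
the uniform-weight objective (the former is never allowed to exceed the
latter), the effective ensemble size $1/\sum_k w_k^2$, and a
rank-deficiency flag: conformers with identical secondary-structure
strings have identical prediction rows, so their individual weights are
not identifiable — `collapse_duplicate_conformers()` merges such groups
when a uniquely identified mixture is needed.

`ensemble_summary()` converts weights into per-residue probabilities
$p_S(i) = \sum_k w_k \, 1[s_k(i) = S]$ and reports per-nucleus RMSD and
correlation between fitted and experimental shifts.
`compare_variants()` differences two summaries over a region —
typically each variant's own polyQ tract — in the shared normal-length
(10Q) numbering frame.

## HDX classification

The experimental readout is presence/absence of HSQC peaks after 15, 60
and 120 min of exchange against an H₂O control, not quantitative
protection factors. `classify_hdx()` operationalises this: an amide is
a slow exchanger when its intensity ratio to control at the reference
time (default 15 min) is at least a threshold (default 0.2, exposed).
Prolines and residues without a control peak are excluded; slow
unassigned glutamines in the tract get their own marker, mirroring how
expanded-tract spectra are annotated. A slope variant fits a log-linear
decay over all time points and thresholds the fitted ratio at the
reference time instead. Classification is invariant under uniform
intensity rescaling, and raising the threshold can only shrink the slow
set.

## The synthetic-data generator

`make_scenario()` builds a 62-residue stand-in for the fragment in
block order NT–ARR1–ARR2–polyQ(n)–PRR. The deposited wild-type sequence
is not bundled, so residue identities are a documented stand-in chosen
to honour the analysis landmarks: ARR2 is the eight-alanine block
21–28 (Ala24–Ala28 inside it), Arg29 separates it from the tract, the
tract is Q30–Q39 at normal length (so the 3rd/9th glutamines used for
assignment anchoring are positions 32/38) and the tail is proline-rich.
Expanded presets insert glutamines after position 39 and map them
outside the 10Q numbering frame (`map10q`), which is how unassigned
tract residues are reported.

The per-residue helix propensity is the scenario's ground truth:
0.75 over ARR2, 0.35 over ARR1, 0.6 at Arg29, ≤ 0.18 decaying along a
normal tract, and for expanded presets 0.05 + 0.65·exp(−(i−1)/6) along
the tract — elevated next to the ARR and decaying with a ~6-residue
length constant, the helix-propagation shape the shift analysis is
meant to detect. The helix-broken preset (an Ala26→Pro substitution
with ARR propensity ≤ 0.05) emulates helix-disrupting mutants.

`sample_pool()` needs contiguous helical segments whose per-residue
frequency across the pool still equals the propensity profile. It
thresholds a latent AR(1) Gaussian field (autocorrelation 0.9) at
qnorm(propensity): the marginal is then exact by construction while
states are serially correlated into runs. Runs shorter than 4 residues
are repaired mass-neutrally — a run of length L is extended to 4 with
probability L/4 and deleted otherwise, so in expectation it still
contributes L helical residues. Residual local bias survives at sharp
propensity steps and chain termini (a few hundredths; the ARR2-mean
agreement at a 500-conformer pool is within ±0.05, which is what the
test suite asserts). A small strand propensity (0.03) adds extended
runs to the coil background. Dihedrals are drawn inside the matching
basin with jitter; coil dihedrals come from polyproline-II-like and
left-handed pockets that lie outside both basins, so the assignment
recovers the intended states exactly up to the terminal-residue and
minimum-run rules.

`synth_experimental_shifts()` averages the pool's predicted shifts
under known ground-truth weights and adds Gaussian noise (default
0.05 ppm, roughly the reproducibility of carbon shifts between
prediction and experiment); `synth_hdx()` gives residues with
propensity ≥ 0.5 a slow decay (ratio ≈ 0.7 at 15 min) and all others a
fast one (≈ 0.02), with 5 % multiplicative log-normal noise. Each
scenario derives fixed per-operation RNG sub-streams from its seed, so
adding one operation never perturbs another's draws.

What the generator does *not* emulate: force-field physics (no
energies, no temperature), realistic shift predictor error structure
(the forward model is the same one used in fitting, so synthetic
recovery tests validate the estimator, not predictor accuracy),
chemical-exchange broadening, or aggregation. Passing the synthetic
suite therefore shows that the estimation machinery is correct and
well-conditioned at the stated noise levels — not that any particular
experimental dataset will be fit well.

## Numerical and design choices

* **Fit observables.** Which nuclei enter the fit is an argument; the
  synthetic experiments use all five so that a 100-conformer problem
  has ≥ 300 observables (the expanded-tract construct, 74 residues,
  provides 336 — glycine Cβ and proline H/N do not exist). Recovery
  experiments use the 22Q preset for exactly this reason.
* **Ground-truth mixtures** in recovery experiments are sparse (10
  active of 100), matching how a least-squares fit over a large pool
  concentrates weight, and duplicate secondary-structure strings are
  merged before comparison since their split is unidentifiable.
* **Problem sizes.** Tests and the demonstration pipeline run pools of
  25–500 conformers of 62–74 residues; the exact QP solves in
  milliseconds at K = 100, and a full synthetic pipeline run takes
  under a second.
* **Determinism.** The QP solver is exact and deterministic; pipelines
  re-run byte-identically for a fixed seed.
* **Degenerate inputs.** Single-conformer pools return weight 1;
  all-coil pools predict the random-coil vector for any weights;
  glycine Cβ observables are rejected by name; empty windows yield NA
  scores rather than extrapolations.

## Known limitations

The dihedral-basin assignment ignores hydrogen-bond geometry; the SSP
reference offsets and random-coil values are bundled averages, not
re-referenced per dataset (deposited-data analyses should treat
absolute score levels as approximate and prefer bound-type statements,
e.g. "ARR2 scores exceed 0.3"); and the linear forward model cannot
reproduce predictor-specific biases. The reweighting returns one
least-squares optimum on the simplex — with nearly collinear pools the
weight vector itself is ill-determined even when the per-residue
probability profile (which is what the shifts actually constrain) is
stable; the effective ensemble size and rank-deficiency flag are there
to make that visible.
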