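---
title: "Methods: CSP titration analysis, K_D estimation and restraint generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSP titration analysis, K_D estimation and restraint generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspkit)
```

## The measurement and its model

A ¹⁵N-labelled protein is titrated with an unlabelled peptide and a 2D
¹H-¹⁵N HSQC is recorded at each ligand:protein ratio. When binding is in
fast exchange on the chemical-shift timescale, each amide peak sits at the
population-weighted average of its free and bound positions and glides
continuously toward the bound position as ligand is added. Two consequences
drive everything in this package:

1. the observed perturbation of residue $i$ at total ligand $L$ is
   $\Delta\delta_{obs,i}(L) = \Delta\delta_{max,i} \cdot f_b(L)$ — the
   residue-specific saturation amplitude times a residue-independent
   fraction bound; and
2. $f_b$ follows the 1:1 equilibrium mass balance.

Perturbations are always measured against the apo reference, never between
consecutive points, and combine both axes as
$\Delta\delta_{obs} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 5)^2}$.
The nitrogen divisor 5 compensates the wider ¹⁵N dispersion and is the
package default; `nitrogen_scale` is exposed because other weightings
(e.g. gyromagnetic-ratio-based ≈ 0.10–0.20 scalings expressed as divisors)
circulate in the literature.

### Why the quadratic isotherm is the default

`fraction_bound()` offers the exact depletion form
$f_b = \big[(P+L+K_D) - \sqrt{(P+L+K_D)^2 - 4PL}\big] / 2P$ in *total*
concentrations, and the dilute-limit hyperbola $L/(L+K_D)$, which treats
total ligand as free ligand. At NMR concentrations (here 0.25 mM protein)
with affinities of 200–2600 μM, protein and $K_D$ are the same order of
magnitude, so ligand depletion is material: fitting the hyperbola to
depletion-generated data biases $K_D$ upward. The quadratic form is
therefore the default everywhere; the hyperbolic form is kept for
comparison, and the two are asserted to agree within 1% whenever
$P \le K_D/100$. Which functional form the original curve-fitting software
used in comparable studies is generally not reported; recording `kind` in
every fit report keeps this choice explicit. The discriminant
$(P+L+K_D)^2 - 4PL \ge (P-L)^2 + K_D^2 > 0$ analytically; negative
round-off below $10^{-12}$ is clamped to zero before the square root.

## Per-residue fitting and aggregation

`fit_residue()` minimises the unweighted residual sum of squares of
$\Delta\delta_{max} f_b(L; K_D)$ over $(K_D, \Delta\delta_{max})$ with
bounds $K_D \in [10^{-3}, 10^3]$ mM and $\Delta\delta_{max} \in [0, 10]$
ppm, using bounded Levenberg–Marquardt (minpack.lm). Weak binders produce a
shallow, banana-shaped RSS valley in which a single start can stall, so a
deterministic multistart over $K_D \in \{0.05, 0.2, 0.5, 2, 5\}$ mM (with
$\Delta\delta_{max}$ started at the endpoint CSP) is run and the lowest-RSS
solution kept; identical inputs therefore always return identical
estimates. Residuals are unweighted because per-point peak-position
uncertainties are rarely available. Degenerate inputs are reported, not
fitted: an all-zero curve returns `converged = FALSE` with note
"no perturbation"; a curve that is already saturated at the first non-zero
point drives $K_D$ onto its lower bound and is flagged
`identifiable = FALSE`.

The aggregate affinity is the arithmetic mean of converged per-residue
$K_D$ values and its error their sample standard deviation ($n-1$; zero
and flagged when only one residue contributes). This mirrors the common
practice of quoting the spread of several independent single-residue fits
as the error. An alternative global fit — one shared $K_D$, per-residue
amplitudes profiled analytically (the model is linear in
$\Delta\delta_{max}$ at fixed $K_D$) and a 1-D minimisation over
$\log K_D$ — is available as `method = "global"`; it yields no spread and
is intended as a consistency check, not the default.

**Partial saturation.** The weakest complex in the study design
(2574 μM at 0.25 mM protein, endpoint ratio 1:30) ends its titration at
$f_b \approx 0.74$; its $K_D$ is an extrapolation. `aggregate_kd()` flags
any series whose *median* endpoint fraction bound (recomputed at the fitted
$K_D$) is below `saturation_floor = 0.8`. The floor separates that design
(≈ 0.74) from the next-weakest one (≈ 0.91) with margin on both sides; it
is a property of the flag, not a fit parameter.

## Residue selection and the significance floor

`selection_rule()` has two modes. Explicit lists reproduce the practice of
fitting hand-picked cleft resonances. Threshold mode selects residues whose
endpoint CSP exceeds `mean + threshold_sigmas × SD` (default 1 SD) of all
observed endpoint CSPs **and** an absolute floor `min_csp = 0.01` ppm. The
floor is deliberate: on a pure-noise profile, any relative mean + k·SD cut
always sits inside the tail of a continuous distribution, so without a
floor some residues are flagged in almost every noisy null dataset (and on
an all-zero profile the cut degenerates to 0 ≥ 0, selecting everything).
0.01 ppm is conservative relative to typical weighted peak-position noise
(≲ 0.003 ppm here) and an order of magnitude below genuine binding
responses (0.02–0.36 ppm weighted in the generator); detection of
displacements is insensitive to it across the tested range, while the null
false-positive rate drops to essentially zero.

The same rule drives `compare_conditions()`, whose statistic is the
weighted CSP formula applied to inter-condition differences. Residues
missing on either side are reported as not comparable rather than zero —
exchange-broadened peaks must not masquerade as unperturbed. Cleft-residue
exclusion in `interface_patch()` is user-supplied: which residues line the
canonical groove is prior structural knowledge, not something this
computation can infer.

## Restraints and structure mapping

`write_air_tbl()` serialises active/passive selections as one CNS-style
`assign` statement per active residue against the OR-combination of the
partner's active ∪ passive residues, with a distance triple defaulting to
2.0 / 0.0 / 2.0 Å (the common convention for ambiguous interaction
restraints; configurable). Selections are residue-level, since CSP data
identify residues, not atoms. Passive residues are caller-supplied:
automatic passive detection requires solvent-accessibility computation on a
structure and is the docking engine's job. `read_air_tbl()` inverts the
writer exactly, which the tests exercise on randomized sets.

`map_to_bfactor()` paints per-residue values into the B-factor column
(61–66) of ATOM/HETATM records by fixed-width substitution, leaving every
other byte of the file untouched. Default scaling is linear to
[0, 99.99] because colour gradients are relative; `scale = "raw"` writes
values as-is. Unmapped residues of the target chain receive the sentinel
−1.00 (a "no data" class distinct from a true 0) or are left untouched
under `missing_policy = "skip"`. The B-factor field holds two decimals, so
a scaled value such as 49.995 is stored as its `%6.2f` rendering.

## What the synthetic generator does and does not emulate

`generate_series()` draws apo peaks uniformly (¹H ∈ [6, 10] ppm,
¹⁵N ∈ [100, 135] ppm), assigns a responding subset (default 6 of 100
residues) per-residue amplitudes uniform in ¹H ∈ [0.02, 0.3] ppm and
¹⁵N ∈ [0.1, 1.5] ppm — typical HSQC titration magnitudes — with random
shift directions per residue and axis (exercising the statistic's sign
invariance), moves peaks by the quadratic $f_b$, and adds fresh Gaussian
noise (σ_H = 0.002 ppm, σ_N = 0.01 ppm by default) at every non-apo point.
Non-responding residues receive noise only, providing the null population
the threshold rule needs. Missing residues (prolines, overlap) are simply
absent from every table. The preset scenarios in `pdz_scenarios()` fix
0.25 mM protein — the midpoint of the 0.1–0.5 mM range such experiments
use, and a value at which depletion genuinely matters — with ratio
schedules 0, 1, 3, 5, 10, 20, 30 (0, 2, 4, 6, 8, 10 for the short-schedule
scenario) and the six studied affinities as ground truth.

Not emulated: exchange broadening and intensity loss, peak overlap and
mis-assignment, intermediate/slow exchange, baseline drift between spectra,
and dilution of the protein on ligand addition (the manifest accepts
per-point concentrations if a user wants to model it). Passing
parameter-recovery tests on these synthetics therefore validates the
estimator machinery under the model's own assumptions — it cannot certify
performance on spectra that violate fast exchange.

## Peptide masses

`peptide_mass()` sums standard residue masses (monoisotopic to 5 decimals,
or average) plus one water, with an optional N-terminal acetyl
(+42.01057 Da monoisotopic). The default is the free peptide even though
synthetic titration peptides are commonly acetylated, because
vendor-printed masses usually match the unmodified monoisotopic sum — as
the dodecapeptide worked example does to 2 decimals. Printed masses that
match neither form occur (transcription or vendor rounding); the package
makes the computed convention explicit rather than chasing them.

## Problem sizes and numerical conventions

Tests and the acceptance script use 100-residue constructs, 6–7 titration
points, 200-seed Monte-Carlo batches for the differential specificity
checks and 50 replicates for the noisy-estimator check — sizes chosen so
the complete validation runs in well under a minute while keeping binomial
confidence on the rate checks tight. All concentrations are mM internally;
$K_D$ crosses to μM only at the reporting boundary (×1000). Serialized
floating-point outputs are written at 6 decimals for diff-stable testing;
fitting is bit-deterministic given identical inputs. Seeds are mandatory
for simulation; the generator restores the caller's RNG state.

## Known limitations

- Per-residue $K_D$ confidence beyond the inter-residue spread (e.g.
  bootstrap over points or propagation of peak-position uncertainty) is not
  implemented; the spread is what is reported.
- Only 1:1 binding: no two-site, cooperative or ternary models, by design —
  each domain-peptide interaction is treated independently.
- No NMR-STAR/BMRB parsing, no spectral processing or peak picking: input
  begins at per-residue peak lists.
- mmCIF structures are not supported by the B-factor mapper in this
  version.
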