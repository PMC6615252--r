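# cspkit

Analysis of protein–ligand titrations followed by NMR chemical shift
perturbation (CSP), for spectroscopists and structural biologists studying
weak protein–peptide interactions — the regime typical of PDZ-domain /
C-terminal-peptide recognition, where dissociation constants (hundreds of
micromolar to millimolar) are comparable to the protein concentration in the
NMR tube and binding is in fast exchange.

## What it computes

**Weighted CSP.** For each backbone amide, the perturbation relative to the
ligand-free (apo) spectrum is

$$\Delta\delta_{obs} = \sqrt{(\Delta\delta_{^1H_N})^2 +
\left(\frac{\Delta\delta_{^{15}N}}{5}\right)^2}$$

with the conventional nitrogen scale of 5 (configurable).

**K_D fitting.** In fast exchange the observed CSP of a residue is the
saturation amplitude times the fraction of bound protein,
$\Delta\delta_{obs}(L) = \Delta\delta_{max}\, f_b(L)$, with $f_b$ from the
exact 1:1 mass balance in total concentrations,

$$f_b = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2P},$$

which accounts for ligand depletion (the dilute-limit hyperbola
$L/(L+K_D)$ is available for comparison). Each selected residue is fitted by
bounded nonlinear least squares over $(K_D, \Delta\delta_{max})$ with a
deterministic multistart; the reported affinity is the mean of the
per-residue $K_D$ values and its error their sample standard deviation. A
partial-saturation flag marks series whose endpoint fraction bound stays
below 0.8, where $K_D$ rests on extrapolation.

**Differential CSP.** The same weighted statistic applied residue-by-residue
between two matched conditions (e.g. an isolated domain vs the same domain
in a tandem construct) locates allosteric or inter-domain interface patches;
significant residues outside the canonical binding cleft can be exported as
CNS-style ambiguous interaction restraints (`.tbl`) for data-driven docking,
or painted onto a PDB B-factor column for structure colouring.

**Synthetic titrations.** A generator produces HSQC titration series with
the exact statistical structure the analysis assumes (depletion isotherm,
per-residue amplitudes and shift directions, Gaussian peak noise, missing
prolines, partial-saturation designs), so the whole pipeline is testable
with known ground truth.

## Worked example

```r
library(cspkit)

spec <- synthetic_spec(K_D_true_uM = 286, seed = 7)   # 0.25 mM protein,
g    <- generate_series(spec)                         # ratios 0..30
fit  <- fit_series(g$series, selection_rule("threshold"))
fit
#> <kd_fit> K_D = 292 +/- 15 uM (6 residues, per-residue quadratic fit)
tidy(fit)[, c("residue_index", "K_D_uM", "delta_max", "endpoint_fraction_bound")]
#> # A tibble: 6 x 4
#>   residue_index K_D_uM delta_max endpoint_fraction_bound
#> 1             3   284.    0.146                    0.962
#> 2            17   277.    0.164                    0.963
#> 3            61   304.    0.240                    0.960
#> 4            64   287.    0.278                    0.962
#> 5            78   283.    0.250                    0.962
#> 6            81   316.    0.0769                   0.958
peptide_mass("MFRDFDYIADWC")  # monoisotopic, free termini
#> 1580.64
```

The six threshold-selected residues each recover the generating 286 μM
affinity to within the noise; their mean ± SD (292 ± 15 μM) is what the
package reports as the measured K_D. `autoplot(fit)` overlays the fitted
isotherms on the per-residue CSP curves.

A shell entry point wraps the same functions
(`inst/exec/cspkit <simulate|csp|fit|diff|restraints|map|mass> ...`).

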