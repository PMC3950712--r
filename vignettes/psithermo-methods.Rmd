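---
title: "Two-state melting analysis and nearest-neighbor thermodynamics of pseudouridine-containing RNA duplexes"
author: "psithermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state melting and nearest-neighbor energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psithermo)
```

## Scope

`psithermo` implements the two classical, complementary routes to the
hybridization thermodynamics of short RNA duplexes — optical melting
analysis and nearest-neighbor (NN) free-energy prediction — for duplexes
that may contain pseudouridine (Ψ, encoded `P`), G-U wobble pairs and
single dangling ends. It targets exactly the experimental design used for
modified-nucleotide thermodynamics: non-self-complementary 8-9-mers
melted at nine strand concentrations between 10⁻⁶ and 10⁻³ M in 1 M NaCl,
analysed with a two-state model, and compared against NN predictions and
against isosequential duplexes with U in place of Ψ.

## The two-state model

The duplex is assumed to be all-or-none: only full duplex AB and free
strands A, B (each at total concentration $C_T/2$) are populated, so a
single temperature-independent pair $(\Delta H^\circ, \Delta S^\circ)$
describes the transition (no heat-capacity term). With
$K(T) = \exp(-\Delta G^\circ(T)/RT)$ and
$\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$, the fraction of
strands paired $\alpha$ solves

$$K(T) = \frac{2\alpha}{(1-\alpha)^2\, C_T},$$

a quadratic whose root in $[0,1]$ the package evaluates in the
cancellation-free form $\alpha = b / (b + 1 + \sqrt{2b+1})$ with
$b = K C_T$ (log-space asymptotics once $\ln b > 40$). Setting
$\alpha = 1/2$ gives the concentration-dependent melting temperature

$$T_m^{-1} = \frac{R}{\Delta H^\circ}\ln\frac{C_T}{4} +
             \frac{\Delta S^\circ}{\Delta H^\circ},$$

with $R = 1.9872$ cal mol⁻¹ K⁻¹. Units follow the field's conventions:
kcal/mol for $\Delta H^\circ$ and $\Delta G^\circ$, cal mol⁻¹ K⁻¹ ("eu")
for $\Delta S^\circ$, Kelvin internally and degrees Celsius at the
interfaces, $\Delta G^\circ_{37}$ evaluated at 310.15 K. Energies are
stored with the formation sign (negative = stabilizing); report writers
print magnitudes to match the conventional $-\Delta H^\circ$ table
layout. A `molecularity = 1` switch exposes the self-complementary
variant ($C_T$ in place of $C_T/4$) but none of the shipped reference
data exercise it.

## Melting curves and the two analysis routes

The observable is absorbance at 260 nm, modeled as a population-weighted
mix of two linear baselines,

$$A(T) = \alpha(T)\,(m_{ds}T + b_{ds}) + (1-\alpha(T))\,(m_{ss}T + b_{ss}).$$

**Route 1 — individual curve fits.** Each curve is fit by
Levenberg-Marquardt least squares over six parameters
$(\Delta H^\circ, \Delta S^\circ, m_{ss}, b_{ss}, m_{ds}, b_{ds})$.
Starting values: baselines from linear fits to the outer 15% of the
temperature range; $T_m$ from the extremum of a 5-point-smoothed
numerical derivative; $\Delta H^\circ = -75$ kcal/mol with
$\Delta S^\circ$ implied by the $T_m$ guess. Iterations are bounded at
500 with a $10^{-10}$ tolerance on the relative residual change. Curves
whose shape a single straight line explains (flat or purely linear input)
raise "no transition detected" before any optimization. Per-duplex values
are the means over curves, with the scatter across curves as the sd.

**Route 2 — the $T_m^{-1}$ versus $\ln(C_T/4)$ plot.** Each curve's
$T_m$ is taken from its own fitted $\alpha = 1/2$ point — not from the
derivative maximum, which for a bimolecular melt sits systematically
about 1 °C away from $\alpha = 1/2$. Ordinary least squares of
$T_m^{-1}$ on $\ln(C_T/4)$ then gives
$\Delta H^\circ = R/\text{slope}$ and
$\Delta S^\circ = R\,\text{intercept}/\text{slope}$. The relation is
exactly linear under the model, so noiseless points are recovered to
machine precision. Standard deviations come from the regression
covariance by first-order (delta-method) propagation — how the original
instrument software derived its sds is not documented, so this
well-defined choice is stated as this package's convention.

**Two-state criterion.** The approximation is accepted when the two
routes' enthalpies agree within 15%:
$|\Delta H_a - \Delta H_b| / \overline{|\Delta H|} \le 0.15$. The shipped
reference compilation contains one melt (central U-G context) with two
observed transitions; its published enthalpy pair (−105.9 vs −76.8
kcal/mol, a 32% disagreement) is flagged, not modeled — sequential or
multi-state fitting is out of scope.

## Nearest-neighbor free-energy engine

$\Delta G^\circ_{37}$ of a duplex is the sum of dinucleotide stack terms
over adjacent pairs, helix initiation (+4.09 kcal/mol), terminal-pair
penalties, and single dangling-end terms. Stack keys are written
`"XY/WZ"` (top 5'→3' / bottom 3'→5') and normalized under 180° rotation,
so each physical stack has exactly one parameter and predictions are
invariant under reading the duplex from the other strand. Terminal
penalties apply to A-U (+0.45), G-U (+0.45) and Ψ-A (+0.31) ends; G-C
ends carry none.

Parameter provenance (each entry carries its citation tag in the shipped
`extdata/nn_parameters.tsv`):

* **Watson-Crick** stacks, initiation and the terminal A-U penalty: the
  Xia et al. (1998) set at 2-decimal precision.
* **G-U wobble** stacks: the Turner 2004 compilation, except the two
  terminal-addition motifs `5'UC/3'GG` (−2.25) and `5'GU/3'CG` (−2.60),
  which follow the revised G-U parameter lineage (Chen et al. 2012) that
  makes G-U pairs adjacent to G-C markedly more stable. Mixing the two
  lineages means duplexes with *internal* G-U pairs in G-C contexts are
  predicted on the older values; this only affects cross-checks, and the
  provenance column makes the seam explicit.
* **Ψ-A** stacks and the terminal Ψ-A penalty (Hudson, Dean & Znosko
  2013 lineage): only the four stack contexts pinned down in the primary
  literature are shipped — `5'PC/3'AG` = −2.49, `5'GP/3'CA` = −3.29,
  `5'AP/3'UA` = −2.80 and `5'PU/3'AA` = −2.74 (the latter two from the
  stated U→Ψ enhancements of −1.70 and −1.81 kcal/mol over their
  Watson-Crick equivalents). The remaining four Ψ-A contexts
  (`PA/AU`, `PG/AC`, `CP/GA`, `UP/AA`) are deliberately absent: published
  duplex-level predictions for them were made against a different
  Watson-Crick background and cannot be coherently decomposed onto the
  Xia background used here (back-computing one quoted context from a
  published duplex prediction shifts it by ≈0.5 kcal/mol). Predictions
  touching them raise an informative error instead of guessing.
* **Dangling ends**: the Turner 2004 5'/3' dangle tables. Dangling Ψ has
  no published parameter and raises "unparameterized context".
* Internal Ψ-G, Ψ-U and Ψ-C pairs have no NN parameters anywhere in the
  literature; the engine refuses them by name. The measured
  substitution-increment tables shipped with the package are the
  empirical stand-in: they are measurements, not fitted parameters, and
  are never silently folded into predictions.

Increment arithmetic is exact bookkeeping: a terminal addition is
predicted as (new stack) + (new terminal penalty) − (old terminal
penalty), e.g. −2.35 + 0.45 = −1.90 kcal/mol for a 5'-terminal U-A pair
in the `5'UC/3'AG` context and −2.49 + 0.31 = −2.18 for its Ψ-A
counterpart; measured increments are differences of measured
$\Delta G^\circ_{37}$ values with root-sum-square sd propagation,
conventionally taken from the $T_m^{-1}$-plot route.

## Extinction coefficients

Strand concentrations follow Beer-Lambert with the standard
nearest-neighbor 260-nm extinction model
($\varepsilon = 2\sum\varepsilon_{\text{di}} -
\sum_{\text{interior}}\varepsilon_{\text{mono}}$). Ψ is treated as U by
default — its true $\varepsilon_{260}$ is ≈20% smaller, and the
`psiScale` argument quantifies the consequence: for the 9-mers in the
reference set the concentration bias is ≈2%, negligible next to fitting
error.

## The synthetic-data generator

`generateDataset()` emulates the reference experimental design: nine
log-spaced concentrations over $10^{-6}$–$10^{-3}$ M, a 0–90 °C grid in
1 °C steps, linear baselines, additive Gaussian absorbance noise with a
fixed seed. Published tables report no absorbance amplitudes or baseline
slopes, so the defaults are stated conventions: duplex baseline
$0.92 + 4\times10^{-4}T$, single-strand baseline $1.10 + 8\times10^{-4}T$
(≈20% hyperchromicity, typical of short RNA melts, and irrelevant to the
recovered thermodynamics by construction), and noise sd of 0.2% of the
curve amplitude, the precision of a well-behaved UV melter. What the
generator deliberately does *not* emulate: baseline curvature,
temperature-lag and evaporation drift, aggregation at high $C_T$, and the
two-transition behaviour of non-two-state melts. Passing round-trip tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every instrumental pathology.

Test problem sizes are chosen to probe each claim at desk scale: 20-seed
Monte-Carlo sweeps for the two-state criterion, 25-replicate sweeps for
noise-monotonicity, single-curve fits elsewhere.

## Numerical and design choices

* $\alpha$ is evaluated by the stable closed form above; the independent
  check in the test suite is a 200-step bisection of the mass balance.
* Degenerate fits: monotone/flat curves error out early; a fitted
  non-negative enthalpy is also reported as "no transition detected".
* The fixture tables store printed (rounded) magnitudes exactly as
  published; loaders restore the formation sign. All fixture-based tests
  use table-precision tolerances (2 decimals for energies, 0.5 °C for
  $T_m$ regenerated from rounded $\Delta H^\circ/\Delta S^\circ$), never
  exact floats.
* Published duplex-level Ψ-A predictions and the RNAstructure-style
  predictions for unmodified duplexes are carried in the fixtures as
  cross-checks. The engine reproduces the unmodified-duplex values within
  the 0.1 kcal/mol expected from rounding-variant differences for the
  all-Watson-Crick duplexes (e.g. −12.57 vs the published −12.5), while
  two A-U-rich published values differ by ≈0.2 kcal/mol — consistent with
  that software rounding its working tables to 0.1 kcal/mol.
* Measured-versus-predicted comparisons use a 1 kcal/mol tolerance flag
  applied as $|\Delta| \le 1 + \text{sd}$ ("within experimental error");
  no p-values, matching how such comparisons are made in this literature.

## Known limitations

* No loops, bulges, hairpins, multi-state transitions or heat-capacity
  corrections — the model is exactly the two-state bimolecular duplex.
* Ψ parameters cover Ψ-A contexts only, and only four of eight stacks;
  everything else Ψ is measurement-backed, not predictable.
* The G-U table mixes two parameter lineages (documented per entry).
* The sd model for the $T_m^{-1}$-plot route is regression covariance;
  resampling alternatives would give somewhat different error bars.
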