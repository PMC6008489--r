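---
title: "Profiling a kinase-targeted fragment library: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a kinase-targeted fragment library: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscreen)
```

Fragment libraries are screened at high concentration against kinase
panels to find weak but efficient chemical starting points. The raw
readouts of such a campaign — percent inhibition at a single
concentration across a panel, follow-up dose-response curves on the most
interesting targets, and co-crystal structures of the best fragments —
need a consistent computational layer before they say anything
comparable: potencies must be put on an assay-independent scale,
selectivity must be quantified, and binding-site geometry must be
measured reproducibly. This vignette documents the models this package
uses for each step, the parameters that matter, and the design decisions
that were genuinely open.

## Formula bookkeeping

HRMS characterization lines report the formula of the observed \[M+H\]⁺
ion. The neutral molecule is that formula minus one hydrogen
(`neutral_from_protonated()`), the heavy-atom count (HAC) is the number
of non-hydrogen atoms, and the calculated m/z is the sum of monoisotopic
atomic masses plus the proton mass 1.007276 Da. The proton-mass
convention (equivalently: subtract one electron mass from the H-atom
sum) is the one mass spectrometers calibrate against, and it reproduces
nine of the ten calculated m/z values in the bundled HRMS table
(`inst/extdata/hrms_table.csv`) to within 0.0001 Da. The tenth (the
benzamide analogue, compound 16) was evidently calculated without the
electron correction in the source; its value still agrees within
0.0006 Da, which is the band the test suite asserts. The atomic-mass
table covers H, B, C, N, O, F, Si, P, S, Cl, Br, I — the elements of
small-molecule kinase-inhibitor chemistry; anything else is a parse
error rather than a silent guess. Parenthesised groups and hydrates are
out of scope: no compound in this chemistry needs them.

## From IC50 to comparable affinities

Panel assays run at different ATP concentrations, so IC₅₀ values are not
comparable across kinases. For an ATP-competitive inhibitor the
Cheng–Prusoff relation

$$K_i = \frac{\mathrm{IC}_{50}}{1 + [\mathrm{ATP}]/K_{m,\mathrm{ATP}}}$$

removes the assay dependence. `cheng_prusoff_ki()` implements exactly
this: $K_i = \mathrm{IC}_{50}$ at vanishing ATP, half of it at ATP
$= K_m$, strictly decreasing in ATP. Tight-binding (Morrison)
corrections and non-competitive mechanisms are out of scope — fragment
potencies here are far from the enzyme concentration.

Ligand efficiency is the binding free energy per heavy atom,
$\mathrm{LE} = 1.37 \cdot \mathrm{p}K_i / \mathrm{HAC}$ in kcal·mol⁻¹
per heavy atom, where 1.37 kcal/mol is the value of one pK unit at
298 K. The constant is fixed rather than fitted: recomputing the
published LE table for every non-censored pair with a formula-backed HAC
(24 pairs, `analysis/04_ligand_efficiency.R`) reproduces 16 of 24
printed 2-dp values exactly and all but three within 0.015 kcal/mol/HA;
the three Aurora A cells that resist (compounds 2, 3 and 5, off by
0.028–0.033) are inconsistent with *any* single constant given the other
cells, so they are documented as source inconsistencies rather than
absorbed by a bespoke temperature. Censored potencies (`">100"`) are
first-class: they keep their bound, are excluded from LE and from
selectivity numerators, and render as `> x` with a blank LE in reports.

All concentrations are µM internally; the only molar conversion happens
inside `pki()`. Reported values round half-up (0.345 → 0.35, matching
the printed tables) at presentation only — `round_half_up()` exists
because base R rounds half to even.

## Selectivity over a panel

For a compound screened at one concentration against $K$ kinases,
$S_{\mathrm{compound}}(\theta)$ is the fraction of *evaluated* kinases
inhibited strictly above $\theta$\%; $S_{\mathrm{kinase}}(\theta)$ is
the mirror over compounds. Two decisions here were open:

* **Strict inequality.** A measurement of exactly $\theta$ does not
  count as a hit. The convention is stated with ">" in the field's
  definition of the score and matters only for ties, which real-valued
  noise makes measure-zero but synthetic data can produce.
* **Missing cells shrink the denominator.** A promiscuous compound
  reported as inhibiting 23 panel members above 50% with a score of
  0.92 is only consistent with 23/25 — one measurement excluded — not
  with a fixed denominator of 26. Scores are therefore stored as exact
  integer pairs (hits, evaluated) and only rounded in reports.

Values outside \[0, 100\] are legitimate screen output (noise around
fully-inhibited or inactive wells); the container accepts \[−100, 200\]
and rejects anything wilder as a unit error.

## Dose-response fitting

Curves are fitted with the four-parameter logistic
$r(c) = b + (t - b)/(1 + (\mathrm{IC}_{50}/c)^h)$ by
Levenberg–Marquardt least squares (via `minpack.lm`), with IC₅₀
optimized as log₁₀(IC₅₀) and the Hill slope as log(h), so both stay
positive without constraints. Defaults fix $b = 0$, $t = 100$: the
mobility-shift readout is normalized to controls, and freeing the
asymptotes on 8-point fragment curves mostly trades variance for bias.
`free_asymptotes = TRUE` fits all four.

Initialisation is deterministic: bottom = min response, top = max
response, IC₅₀ = the tested concentration whose response is nearest the
midpoint, $h = 1$. Convergence tolerances are 10⁻¹⁰ on relative
residual-sum-of-squares and parameter change with at most 500
iterations; on noiseless synthetic curves this recovers generating
parameters to better than 10⁻⁶ relative error, which the tests assert
for $h \in \{0.5, 1, 2\}$. Two failure modes are handled as data, not
exceptions: flat responses return `converged = FALSE`, and a fitted
IC₅₀ above the highest tested concentration is reported censored at
that concentration (`> c_max`) because the data cannot support the
extrapolated point estimate.

## The synthetic screen generator

There is no public per-well screen matrix to regress against, so the
package ships a generator (`sim_config()`, `sample_truth()`,
`forward_screen()`, `forward_curves()`) whose point is to make every
pipeline stage testable against known truth. It emulates the *study
conditions*: a 26-kinase panel, a 100 µM single-point screen, assays at
ATP = Km (so IC₅₀ = 2·K_i; the ratio is configurable per kinase over
0.1–10), 8-point half-log triplicate follow-up curves from 100 µM, and
a compound library of three archetypes:

* **promiscuous** — pK_i ~ N(5.0, 0.5) across all kinases, the
  profile of a non-selective hinge-binding fragment;
* **selective** — baseline pK_i ~ N(3.0, 0.3) with 1–3 target kinases
  boosted by +1.5 units, the profile of a fragment with a real but
  narrow footprint;
* **inactive** — pK_i ~ N(2.5, 0.3) everywhere.

The default mix (0.25/0.50/0.25 by largest-remainder allocation) mirrors
a first-pass fragment library in which most members show narrow or no
activity. Observation noise is additive Gaussian on the percent scale
(sd 5% single-point, 2% curves) — the simplest model consistent with a
normalized biochemical readout; it is *not* a reconstruction of the
actual assay's replicate structure, which is not public. Observed values
are clipped to \[−20, 120\] after noise, mimicking real screen
artifacts, and cells drop out with probability 0.02 to exercise the
missing-data denominators. Under this model the promiscuous archetype
scores a mean S(50%) near 0.9, the selective archetype near 0.06 and
the inactive archetype 0 — the qualitative separation that the real
campaign's 0.77–0.92 / 0.08 / inactive profiles show, and the tests
assert the promiscuous mean within ±0.15 of the 0.77 benchmark.

What passing tests on this generator show is that the *pipeline* —
fitting, conversion, scoring, censoring, missing-data handling — is
correct and unbiased (median absolute pK_i recovery error < 0.05, bias
< 0.02 over 200 simulated curves). What they cannot show is robustness
to real-assay pathologies the noise model omits: plate effects,
correlated replicate errors, compound aggregation at high
concentration, partial inhibition plateaus.

All randomness flows from the config seed through a private RNG stream
(`sample_truth` uses the seed itself; the screen and curve stages use
seed+1 and seed+2 so regenerating any stage is independent of call
order), and the caller's RNG state is restored afterwards. Problem
sizes in the bundled workflow — 24 compounds, 26 kinases, ~160 curves;
200 pairs in the recovery benchmark — are the scale of the real
campaign and keep every run comfortably interactive.

## Contact geometry

`read_structure()` parses fixed-column PDB files via `bio3d`,
then resolves alternate locations (highest occupancy per atom site,
ties to altLoc `A`) and fills missing element symbols from atom names.
Hydrogen bonds use a distance-only criterion: ligand N/O to protein N/O
within 3.5 Å. Structures at the 2.5–3.0 Å resolutions typical of kinase
co-crystals carry no hydrogen positions, and the study-style reports
quote bare donor–acceptor distances, so an angle term would manufacture
precision; the criterion is recorded in the output header.
Donor/acceptor polarity is assigned heuristically from atom identity
(backbone and carboxylate O accept; backbone N, lysine NZ and the other
H-bearing side-chain nitrogens donate; hydroxyls and histidine ring
nitrogens are reported `undetermined` rather than guessed). Lysine NZ
as donor matters here: the weak pyridyl-N⋯catalytic-lysine interaction
at 2.6 Å is picked up by the same N/O rule as the hinge bonds at 2.8
and 2.7 Å. Hydrophobic packing is C–C pairs within 4.5 Å grouped by
residue. Residue numbers are taken verbatim from the file, and
cross-structure comparisons (`compare_pocket_residues()`) take a
user-supplied residue-number map — superposition is deliberately out of
scope.

The bundled coordinate files are *synthetic* fixtures
(`synthetic_mps1_site.pdb`, `synthetic_aurora_a_pocket.pdb`): minimal
hinge sites built to exact distances (2.80/2.70/2.60 Å; packing
residues VAL539/ILE663; gatekeeper MET602 vs LEU210, ILE663 vs ALA273),
not deposited structures. They pin the geometry code down exactly; runs
on real deposited structures go through the same functions with the
relevant ligand residue code.

## Known limitations

* The formula parser rejects parentheses, hydrates, isotopes and
  charge annotations by design.
* LE uses a fixed 1.37 kcal/mol constant; sources that used another
  temperature or rounding path will disagree in the second decimal.
* The 4PL never models biphasic or partial-inhibition curves; flat or
  out-of-range data yield non-converged or censored results.
* The generator's Gaussian, uncorrelated noise understates real
  screen error structure; recovery numbers on it are best-case.
* H-bond detection is distance-only and element-based; it will happily
  report an N·O pair that chemistry would rule out by geometry.
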