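# fragscreen

Analysis toolkit for fragment-based kinase screening campaigns. It covers
the computational layer of a panel-profiling study end to end: bookkeeping
of molecular formulas reported in HRMS characterization lines, conversion
of measured potencies to comparable affinities, selectivity scoring over a
kinase panel, dose-response curve fitting, a ground-truth-labelled
synthetic screen generator for validating the pipeline, and
protein–ligand contact geometry from PDB coordinate files.

## The quantities it computes

- **Heavy-atom count and monoisotopic m/z** from formula strings. HRMS
  lines report the \[M+H\]⁺ ion formula; the neutral molecule is that
  formula minus one H, and m/z = Σ(monoisotopic atomic masses) + 1.007276
  Da (proton mass).
- **Cheng–Prusoff conversion** for ATP-competitive inhibitors:
  K_i = IC₅₀ / (1 + \[ATP\]/K_m,ATP), which makes potencies comparable
  across kinases assayed at different ATP concentrations.
- **Ligand efficiency**: LE = 1.37 · pK_i / HAC in kcal·mol⁻¹ per heavy
  atom, with pK_i = −log₁₀(K_i in molar) and 1.37 = 2.303·RT at 298 K.
- **Selectivity scores**: S_compound(θ) is the fraction of panel kinases a
  compound inhibits by strictly more than θ% at the screening
  concentration (1 = completely non-selective); S_kinase(θ) is the mirror
  over compounds. Missing measurements are dropped from the denominator.
- **Four-parameter logistic (4PL) fits**: response = bottom +
  (top − bottom)/(1 + (IC₅₀/c)^h), fitted by Levenberg–Marquardt with
  IC₅₀ on the log scale, asymptotes fixed at 0/100 by default, and IC₅₀
  beyond the tested range reported as a censored bound.
- **Contact geometry**: hinge hydrogen bonds as ligand/protein N·O pairs
  within 3.5 Å (distance-only criterion) and hydrophobic packing as C–C
  pairs within 4.5 Å.

## Worked example

```r
library(fragscreen)

# benzamide analogue: ion formula from its HRMS line, Ki 5.4 uM vs MPS1
neutral <- neutral_from_protonated("C17H14N3O2")
heavy_atom_count(neutral)                        # 22
round_half_up(monoisotopic_mz(neutral), 4)       # 292.1081
round_half_up(ligand_efficiency(5.4, 22), 2)     # 0.33 kcal/mol per heavy atom

# a 100 uM screen measurement of 80% inhibition implies IC50 = 25 uM
ic50_from_single_point(80, 100)$ic50_uM          # 25
cheng_prusoff_ki(25, atp_conc = 20, km_atp = 20) # 12.5 (assay at ATP = Km)
```

The `analysis/` scripts run the whole pipeline as a narrative workflow on
a seeded synthetic screen (see the methods vignette for what the
generator does and does not emulate):

```sh
Rscript analysis/01_simulate_screen.R      # 24 compounds x 26 kinases + curves
Rscript analysis/02_selectivity_profile.R  # S(50%)/S(80%) tables
Rscript analysis/03_dose_response_potency.R
Rscript analysis/04_ligand_efficiency.R
Rscript analysis/05_hinge_contacts.R
```

On the default seed the workflow prints, among other things: promiscuous
compounds score a mean S(50%) of 0.91 versus 0.06 for selective and 0.00
for inactive ones; the 161 follow-up curves are all fitted with a median
absolute pK_i recovery error of 0.0088 and a mean bias of −0.0006; and the
synthetic hinge site shows the canonical contact pattern (ligand NH to the
hinge carbonyl at 2.80 Å, hinge NH to the ligand carbonyl at 2.70 Å,
catalytic-lysine NZ at 2.60 Å, packing against VAL539 and ILE663).

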