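---
title: "Methods: metabolic-hydrogen accounting for methane-inhibition studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic-hydrogen accounting for methane-inhibition studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenflux)
```

## The problem

Rumen fermentation produces reducing equivalents ([2H]) that are disposed
of mainly by methanogenesis. When an anti-methanogenic compound suppresses
CH4 formation in a dose-dependent way, the [2H] must be redirected:
expelled as H2, captured in formate, incorporated into the more reduced
short-chain fatty acids (propionate, butyrate, valerate), or used for
microbial biomass. `rumenflux` quantifies each of those routes for a
chamber study in which two diet groups of cattle (a roughage hay diet and
a 60:40 hay:concentrate diet, four animals each) pass through an ordered
sequence of periods — control, low, mid and high inhibitor dose, and a
post-treatment recovery — with two 24-h respiration-chamber days per
period.

## Gas flux

Each chamber sampling event yields a window of flow (L/min), temperature,
pressure and chamber/background concentrations (ppm by volume). Treating
ppm as a mole fraction, the ideal-gas law at the window's *measured*
conditions converts the enriched volume flow to mass:

$$\mathrm{rate} = F \cdot (c_{ch} - c_{bg}) \cdot 10^{-6} \cdot
  \frac{P}{RT} \cdot M \quad [\mathrm{g/min}]$$

with $R = 8.314$ kPa L mol$^{-1}$ K$^{-1}$ and molar masses CH4 16.043,
H2 2.016, CO2 44.009 g/mol. Daily production is the duration-weighted mean
window rate scaled to 1440 min, averaged over the chamber days of a
period; yield divides by the animal's dry-matter intake. Negative net
concentrations (chamber below background, possible at near-zero emission)
are kept and flagged rather than clipped: clipping would bias daily means
upward at low emission, exactly where the H2 control periods live.

## Hydrogen stoichiometry

Metabolite flows are not measured in vivo, so concentrations act as
proxies. With C1..C5 the molar concentrations of formate through valerate:

* $\mathrm{HUSr} = 2\,C3 + 2\,C4 + C5$ — [2H] captured in SCFA (each
  propionate or butyrate costs two [2H] pairs relative to acetate, each
  valerate one net).
* $\mathrm{HUFr} = C1$ — [2H] captured in formate.
* $\mathrm{ACL} = \frac{C1 + 2\,C2 + 3\,C3 + 4\,C4 + 5\,C5}
  {C1 + C2 + C3 + C4 + C5}$ — the average chain length of the
  fermentation acid pool.
* non-carboxyl SCFA carbon $= (\mathrm{ACL} - 1) \times$ total SCFA — the
  carbon with energy value to the animal, once every acid's carboxyl
  carbon is discounted.

Two conventions here were genuinely open and are worth stating precisely:

1. **ACL component set.** The chain-length average runs over formate and
   the *straight-chain* acids only; branched iso-butyrate and iso-valerate
   are excluded (they arise from amino-acid fermentation, not from chain
   elongation of the same [2H]-accepting pool). The multiplier "total
   SCFA" is the sum of the six measured acids — iso-acids included,
   formate excluded. This pairing is the one that makes the derived
   column self-consistent with the reported fermentation tables across
   diets and doses; putting iso-acids into ACL or formate into the
   multiplier misses by 7–15%.
2. **HUSr and branched isomers.** By default the C4/C5 classes in HUSr
   are the straight-chain acids, consistent with the ACL convention;
   `include_branched = TRUE` adds $2\,iC4 + iC5$ for users who read the
   class labels inclusively. The stored iso-valerate value includes
   co-eluting 2-methylbutyrate; no split is attempted.

The redirection ratio relates H2 expelled to the CH4 forgone, in mol/day:
$r = \mathrm{H2}/(\Delta \mathrm{CH4})$. Because hydrogenotrophic
methanogenesis consumes 4 mol H2 per mol CH4, $r/4$ is the fraction of
freed [2H] escaping as H2. Both forms are exposed as separate fields
(`mol_h2_per_mol_ch4_decrease`, `h_fraction_recovered`): published
per-animal values of this ratio are consistent with the plain ratio, while
the defining formula in the source literature divides by 4, and the
package declines to guess which one any particular figure shows. The
ratio is undefined when CH4 did not decrease; such rows are `NA` and
flagged.

### Numerical conventions

* Molar percentages must close to 100. The default tolerance is ±0.5
  (raw laboratory profiles); published tables rounded to whole percent
  can miss by slightly more (one diet × dose group sums to 100.61), so
  `pct_tolerance` can be widened explicitly — the acceptance
  recomputations use 1.
* A profile with an empty formate + straight-chain pool has no defined
  ACL and errors; a formate-only profile gives ACL 1 and zero
  non-carboxyl carbon.
* Ratios are computed in full floating point; tabular outputs round to 2
  decimals for display only.

## qPCR quantification

Replicate Cts (triplicates in the emulated assay design) are combined by
arithmetic mean per sample × target; a replicate SD above 0.5 cycles flags
the sample. Relative quantification is the comparative-Ct method:
$\Delta Ct = Ct_{target} - Ct_{reference}$,
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}$, fold
$= 2^{-\Delta\Delta Ct}$, with the total-bacteria assay as reference and
the control period as calibrator. Because the two diets are separate
groups of animals, the calibrator mean is taken within diet. The 2^-ddCt
path assumes 100% efficiency (the method's own assumption); supplying
standard-curve efficiencies switches to the efficiency-corrected (Pfaffl)
form, which reduces to 2^-ddCt at E = 1. Absolute abundance inverts the
calibration line: copies $= 10^{(Ct - b)/m}$, with efficiency
$10^{-1/m} - 1$ required to lie in (0, 1.2].

## Community indices and diversity

Taxon-count tables carry a lineage string per taxon
(`d__...;p__...;...;g__...`). Ratio indices (B:F, A:B, S:B, V:B) are
ratios of summed counts matching lineage filters within a sample —
identical on raw counts and relative abundances, so no rarefaction is
applied by default. Alpha diversity reports observed richness, Shannon
entropy over present taxa, and "estimated species richness" as Chao1 in
the bias-corrected form $S_{obs} + F_1(F_1 - 1) / (2(F_2 + 1))$, chosen
because it stays defined when no doubletons occur; no source estimator was
named, and this is the standard conservative choice.

## Dose × diet statistics

The design is a classic split plot: each animal receives one diet
(between-subjects) and every dose (within-subjects), with animal as the
experimental unit. The balanced sums-of-squares decomposition

$$SS_{total} = SS_{diet} + SS_{animal(diet)} + SS_{dose} +
  SS_{dose\times diet} + SS_{residual}$$

tests diet against the animal-within-diet mean square and dose,
dose × diet and the polynomial contrasts against the within-subjects
residual. Choices made here:

* **Dose spacing.** Contrasts default to equally spaced ordinal levels —
  the default of the mainstream statistics packages this analysis style
  comes from — with actual dose values (e.g. 0, 1.0, 1.6, 2.6 g/100 kg
  liveweight) available via `dose_spacing`; vectors are built by
  Gram–Schmidt and rescaled to the classical integer tables when the
  spacing is equal.
* **No sphericity correction by default.** The univariate
  repeated-measures F tests are reported as-is; the error structure with
  a single within-subjects error stratum is the default and the only one
  exposed, since the emulated analysis reported no correction.
* **LSD.** Pairwise dose comparisons within diet use unadjusted t tests
  on the within error MS (Fisher's LSD after a significant F), with an
  insert-and-absorb compact letter display; significance at P ≤ 0.05,
  tendencies at P ≤ 0.10, both configurable. With zero error variance the
  letters are suppressed and the fit flagged.
* **Strict balance.** Missing cells are not imputed; unbalanced data are
  rejected with a clear message, matching the complete 4-animal-per-diet
  design this decomposition is exact for.

## The synthetic generator

The generator is first-class, tested code: it defines the conditions under
which everything else is verified.

* **Responses.** Each variable is drawn as diet × period mean + a
  persistent animal effect + residual. Group means default to the
  reported study values (`reference_means()`); the post period reverts to
  control (post-treatment emissions were reported to return to control
  levels). The reported pooled SEMs refer to groups of n = 4, so the
  per-observation SD is $sem \times \sqrt{4}$, split evenly between the
  animal effect and the residual (ICC 0.5) — a middle-of-the-road value
  for repeated physiological measurements, configurable. Drawn molar
  percentages are renormalised to close to exactly 100 (the configured
  means are likewise renormalised, since whole-percent rounding leaves
  the published profiles up to 0.61 off closure).
* **Chamber forward model.** A well-mixed single compartment at steady
  state: outlet ppm = background + emission/(flow × molar density ×
  molar mass), at flow 3000 L/min, 298.15 K, 101.325 kPa, 24 windows of
  315 s per chamber day, with Gaussian analyzer noise (0.2 ppm SD)
  on the chamber concentration. Transient mixing dynamics are not
  simulated because the estimator uses steady window averages; with
  noise off, the flux estimator recovers the configured emission to
  machine precision, which the tests assert at 1e-6 relative.
* **qPCR.** Cts are baseline + configured dose shift + animal effect +
  replicate noise. The default methanogen (mcrA) shift reaches 2.6
  cycles at the high dose (≈ a six-fold decrease), protozoa are mildly
  promoted on the concentrate diet, fungi are unaffected.
* **Community.** Phylum proportions follow a configured trajectory
  (Bacteroidetes rising from 0.75 to 0.82, Firmicutes falling from 0.17
  to 0.12, Archaea from 0.010 to 0.002 across doses; control B:F ≈
  75:17). Counts are Dirichlet-multinomial (concentration 200, 10 000
  reads/sample, 6 taxa per phylum with fixed geometric within-phylum
  weights), giving the overdispersion typical of 16S count data while
  keeping the ground-truth ratios closed-form.
* **Reproducibility.** One seed fixes every value; the RNG state is
  restored on exit; `truth_table()` returns every generating parameter
  for recovery tests, and `write_study()` emits CSVs plus a YAML
  manifest from which the bundle is exactly reproducible.

What the generator does **not** emulate — and hence what green tests do
not show about real data: variables are drawn independently (no
correlation between, say, CH4 yield and acetate within an animal beyond
the shared design), there are no carryover or time-order effects within
periods, no read-level 16S artefacts (chimeras, clustering), no diurnal
emission pattern within a chamber day, and per-cell variances are taken
as homogeneous because only pooled SEMs are reported.

## Problem sizes and test budgets

The statistical property checks use sizes chosen to make the assertions
sharp at desk scale: the ANOVA-versus-oracle comparisons use the study's
own 2 × 4 × 4 layout; the null-simulation of the dose test's size uses
1000 replicates (±0.02 band around 0.05); parameter recovery of the B:F
trajectory and mcrA dose effect uses 100 generator replicates, compared
within 2 standard errors on the log scale (the pooled-count ratio
estimator keeps the Dirichlet-multinomial ratio bias an order of
magnitude below those SEs); the interaction-power check uses 200
replicates at a diverging-trend DMI interaction of 3 within-animal SDs,
where the non-centrality (~40) puts true power near 1 so the ≥0.8
assertion is stable.

## Known limitations

* Published *per-animal* derived values (the 1.7/1.4/1.6 redirection
  ratios, the "≈14/37/55%" average CH4 decreases) are not reproducible
  from the printed group means — group-mean arithmetic gives ≈1.43 for
  the low-dose concentrate ratio and ≈21% for the low-dose decrease.
  The package computes per-animal values when animal-level data exist
  and labels group-mean fallbacks as such; tests assert the group-mean
  values and document the discrepancy rather than guessing the
  unpublished per-animal data.
* One reported non-carboxyl cell (hay diet, mid dose, 131) sits ≈3.6 mM
  from the convention-based recomputation (≈127.4), presumably a
  per-animal averaging effect; the other seven cells agree within
  ±1.5 mM, and the four used as acceptance checks agree after rounding.
* The stoichiometry is a proxy ledger, not a full fermentation balance:
  no glucose equivalents, microbial-cell [2H] sinks, or thermodynamic H2
  thresholds, and no prediction of CH4 from SCFA.
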