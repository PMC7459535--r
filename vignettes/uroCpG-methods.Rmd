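---
title: "Methods: discovery and urine-based evaluation of urothelial-cancer methylation markers"
author: "uroCpG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery and urine-based evaluation of urothelial-cancer methylation markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroCpG)
```

# The problem

Urothelial cancer (UC) sheds cells into urine, which makes urine-based DNA
methylation assays an attractive non-invasive diagnostic. The catch is that
urine also collects cells from the prostate and kidney, and most
cancer-associated methylation changes are shared across urological tumor
types. A useful urinary UC marker must therefore be differential in
urothelial cancer *and* quiet in prostate/renal cancer and in all
non-malignant urogenital cells — and the signal must survive the dilution
of tumor DNA by leukocytes and (in women) squamous epithelial cells.

`uroCpG` implements this discovery-and-confirmation workflow end to end:

1. a moderated differential-methylation screen of cancer cell lines
   against primary cells of the same tissue (bladder, prostate, kidney);
2. a second-stage specificity model isolating sites that separate UC cell
   lines from *everything* else;
3. a concordance filter against urine array results, and the choice of an
   amplicon target region;
4. an in-silico model of the MassARRAY EpiTYPER measurement geometry
   (base-specific cleavage, fragment masses, CpG units);
5. diagnostic evaluation of urine cohorts with nonparametric tests,
   ROC/AUC and sensitivity at a preset 95% specificity.

A seeded synthetic-data generator plants ground truth with the statistical
structure the analysis assumes, so every stage is testable against known
answers.

# Beta values, M-values and normalization

Methylation is expressed as a beta value
$\beta = M/(M + U + \alpha)$, with $M$ and $U$ the methylated and
unmethylated probe intensities and $\alpha = 100$ a standard regularizing
offset. Beta values are bounded and bimodal, which makes them poor
material for linear modelling, so all model fitting happens on M-values,
$M = \log_2(\beta/(1-\beta))$, with $\beta$ clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, so fully
(un)methylated sites map to large finite values. Effect sizes are
reported back on the beta scale ($\Delta\beta$, "methylation difference
of 20%" meaning $|\Delta\beta| > 0.2$), because that is the clinically
interpreted quantity.

`simpleScalingNormalize()` implements intensity normalization as
per-sample mean matching: each sample is rescaled so all sample means
equal the grand mean. Mean matching was chosen over sum or median
matching because it is idempotent, scale-equivariant and the most common
reading of "simple scaling"; the choice only affects analyses that start
from raw intensities.

# The moderated differential model

The cell-culture screen has 12 samples: for each of the three tissues,
three cancer cell lines (treated as replicates of the tissue's "cancer"
condition) and one primary culture (a singleton group). The design is a
group-means parameterization with six coefficients; per-tissue effects
are the contrasts (cancer − primary), leaving 6 residual degrees of
freedom.

With a singleton group per tissue, per-site variance estimates are
unstable; the screen therefore borrows strength across sites with the
standard empirical-Bayes hierarchical model: residual variances are
assumed to follow a scaled inverse-chi-square prior with parameters
$(d_0, s_0^2)$, estimated by method of moments on $\log s^2$ (the
digamma/trigamma inversion), and each site's posterior variance is

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}.$$

Moderated t-statistics use $d_0 + d$ degrees of freedom; an F-statistic
over a contrast set is the quadratic form in the contrast covariance,
which reduces exactly to $t^2$ for one contrast. Because the reported
per-tissue significance is a single contrast each, the package takes the
per-tissue moderated statistic as the primary call and offers the joint
F across tissues as an option (`moderatedF()` over all contrasts); the
two coincide in which sites they can flag for a single contrast.

Numerical edge cases: when the observed variances are essentially
constant, the trigamma inversion diverges; the prior df is then capped at
$10^6$ and the prior variance collapses onto the geometric-mean common
variance, so that shrinkage leaves the (constant) variances unchanged.
Sites with missing values in any fitted sample are excluded from fitting
and reported, since a per-site design would otherwise differ between
sites. Multiple testing uses Benjamini–Hochberg throughout with
$\alpha = 0.05$ on adjusted p-values.

The decision matrix classifies each (site, contrast) as −1/0/+1 by
adjusted significance and effect sign. Magnitude thresholds (20%/40%)
are *reporting* bins applied after selection, not part of the decision
rule: the bins use strict `>` at 0.2 and non-strict `>=` at 0.4,
matching the mixed "more than 20%" / "at least 40%" reporting
convention.

The $\Delta\beta$ sign convention is cancer − primary, so
hypermethylation in cancer is positive.

# Two-stage specificity and urine concordance

Stage 1 selects sites differential between UC lines and primary
urothelial cells. Stage 2 fits a second two-group model — the 3 UC lines
against the 9 remaining cultures (prostate/renal lines and all primary
cells) — *restricted to the stage-1 set*, with BH correction within that
subset; "equally well discriminating from everything else" is
operationalized as stage-2 adjusted significance, since no separate
effect-size criterion is imposed at this stage. The pooled 9-sample
group is deliberately heterogeneous: a pan-cancer site leaves a large
within-group variance there, which suppresses its stage-2 statistic —
that is precisely the mechanism that filters out shared cancer effects.

Concordance with urine requires an in-vivo methylation difference
$|\Delta\beta| > 0.2$ (pass 1) and BH-adjusted significance in the
UC-vs-population-control comparison (pass 2). Candidates are ranked by
decreasing $|\Delta\beta_{\text{in vivo}}|$ with ties broken
lexicographically by CpG id, making the ranking a total order. The
amplicon region is anchored at the top-ranked passing site; all
candidate sites on the same chromosome within 300 bp join the region
(the window matches the scale of a typical EpiTYPER amplicon, ~293 bp).
Region output uses 1-based inclusive coordinates; the BED writer
converts to 0-based half-open.

# In-silico EpiTYPER

The EpiTYPER workflow is simulated at the level that matters for assay
design: which CpGs are measurable and which are integrated into one
readout.

* **Bisulfite conversion**: every C not followed by G becomes T; CpG Cs
  remain variable and are carried as IUPAC `Y`. Minus-strand conversion
  is reverse-complement, convert, reverse-complement.
* **Amplicon building**: uppercase primer cores are matched against the
  converted plus strand (forward) and its reverse complement (reverse);
  lowercase tags never participate; `Y` positions match C or T. Zero or
  multiple matches are hard errors naming the primer.
* **Cleavage**: the reverse-strand RNA transcript is cleaved after every
  U (T reaction; the C reaction is available behind a flag). CpG
  positions appear as `R` (A unmethylated / G methylated), so
  fragmentation is independent of methylation state. Fragments tile the
  transcript exactly and each CpG lands in exactly one fragment.
* **Masses**: average ribonucleotide-monophosphate masses (A 329.21,
  C 305.18, G 345.21, U 306.17 Da) plus 18.02 Da terminal water;
  methylation adds exactly 16.00 Da per CpG (A→G substitution in the
  transcript). This simplified average-mass model is sufficient for
  unit/collision logic; it does not attempt adducts or isotopes.
* **Units and conflicts**: CpGs sharing a fragment form one unit,
  labelled by dot-joined ordinals ("5.6"). A unit is unmeasurable when
  any of its informative masses lies within the mass resolution
  (default 16 Da — one methylation shift must be resolvable) of a mass
  producible by a different fragment.

Two CpGs six base pairs apart inside an A-free stretch end up on one
T-cleavage fragment and hence one integrated unit — the geometry behind
a dot-labelled "unit 5.6" readout. The exclusion of edge CpGs with many
missing measurements is *not* a fragmentation property; it is a
data-driven missingness filter (default: drop CpGs/units with >25%
missing within a stratum) in the diagnostics module.

# Diagnostic evaluation

Cohort filtering excludes specimens with ≥500 leukocytes/µL (the
threshold is inclusive) and UC cases lacking UC-history information;
the filter never modifies values and logs every exclusion. Group
comparisons are nonparametric throughout — Mann–Whitney for pairwise
comparisons (exact null distribution when $n_1+n_2 \le 12$ without
ties, otherwise normal approximation with tie and continuity
correction), Kruskal–Wallis with tie correction across the non-UC
groups, Spearman correlation (t approximation) against age — and
two-sided, with raw p-values reported in this module (BH available as
an option). All statistics are stratified by gender and summarized by
medians across CpGs.

ROC curves sweep all distinct thresholds under "higher methylation
predicts UC"; the AUC is computed from ranks with tied pairs credited
0.5, which equals the trapezoidal area and the Mann–Whitney identity
$U/(n_1 n_0)$ — the test suite enforces this identity against the
all-pairs oracle. Sensitivity is read out at a preset 95% specificity:
the maximum sensitivity over thresholds whose specificity reaches the
target, 0 if none does.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
truth:

* **Cell-line screen** (`simulateCellLineScreen()`): 20,000 sites by
  default; baseline methylation from a bimodal beta mixture (60% low,
  mean 0.1; 40% high, mean 0.9); planted categories of 40 UC-specific,
  2,000 pan-cancer and 1,000 bladder–prostate-shared sites with
  $|\Delta\beta| \sim U[0.4, 0.7]$ planted on the beta scale (clipped to
  [0.01, 0.99]); replicate noise $\mathcal N(0, 0.3^2)$ on the M scale —
  mirroring the dual-scale workflow (effects interpreted on beta, models
  fitted on M). Planted directions are hyper-dominant (31/40 for
  UC-specific, 94% elsewhere), and planted baselines leave headroom for
  the effect (hyper sites start low, hypo sites high). The two largest
  UC-specific effects are placed 6 bp apart on one chromosome so region
  picking sees a realistic adjacent pair.
* **Urine array results** (`simulateUrineArrayResults()`): UC-specific
  sites carry an attenuated effect (attenuation 0.8, noise sd 0.05 —
  urine dilutes but largely preserves strong in-vitro differences);
  adjusted p-values come from running the package's own moderated
  pipeline on a simulated 12-vs-12 comparison.
* **Urine cohort** (`simulateUrineCohort()`): group sizes default to the
  reduced clinical collective (207/42 UC male/female, 71 PC, 21 RC,
  41 population controls, 68 urological controls). Observed methylation
  is a tumor-fraction mixture
  $\phi\,\beta_{tumor} + (1-\phi)\,\beta_{bg}$ with
  $\beta_{tumor} = 0.55$ over a low background ($\beta_{bg}$ mean 0.05),
  i.e. a planted case contrast of 0.5. The mean tumor fraction is
  $\phi_0 \cdot r^{\text{recurrent}} / (1 + c\,\text{leuko}/500)$ with
  $\phi_0 = 0.5$ (male) / 0.15 (female — squamous-cell dilution),
  recurrence multiplier $r = 0.7$ and leukocyte coefficient $c = 1$;
  the *realized* per-patient fraction is beta-distributed around that
  mean with concentration 2, and the per-donor background with
  concentration 8 — tumor shedding and background composition vary
  strongly between individuals, and these two dispersions are what
  places the per-unit AUC in the realistic 0.8–0.95 band rather than at
  the near-perfect separation a noiseless mixture would give. Leukocyte
  counts are log-normal with roughly 8% of males and ~30% of females
  above 500/µL; a weak age effect (+0.002/year) is added for male UC.
  Edge CpGs 1 and 13 receive a 40% missingness rate (5% elsewhere),
  emulating their exclusion in practice.
* **Unit readout** (`simulateEpityperReadout()`): unit values are means
  of member CpGs (missing members ignored), truncated noise optional;
  unmeasurable units are emitted as missing.

Everything is deterministic given the seed.

What the generator does *not* emulate: probe chemistry (Infinium I/II)
biases, batch effects, cross-reactive probes, SNP-overlapping probes,
true biological correlation structure between neighboring CpGs, or
realistic tumor-fraction distributions (these are stated assumptions,
not estimates). Passing recovery tests on this generator shows the
pipeline's statistics behave as designed under the assumed model — it is
not evidence about any particular clinical dataset.

# Problem sizes and runtime choices

The defaults used by the test suite and the acceptance script are
deliberately desk-scale: 20,000 sites (the screen's statistical behavior
is insensitive to the site count beyond multiple-testing resolution),
10,000 sites for hyperparameter-recovery simulations, and the reduced
cohort sizes above. The full discovery run completes in a few seconds on
one CPU.

# Known limitations

* Exact site counts from any real 450K dataset depend on reproducing the
  original normalization and preprocessing; the package reports counts
  for whatever matrix it is given.
* The stage-2 specificity criterion is significance-only; a site with a
  tiny but consistent UC-specific shift could pass given enough
  replicates (not an issue at n = 3 + 9 with moderation).
* The EpiTYPER mass model uses average masses and a fixed 16 Da shift;
  real spectra involve adducts, depurination and instrument-dependent
  resolution, so measurability flags are a design aid, not a guarantee.
* Exact Mann–Whitney p-values are only used for small tie-free samples;
  with ties the normal approximation is returned even at small n.
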