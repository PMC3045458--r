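---
title: "Methods: the two-strain age-course screen and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-strain age-course screen and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkscreen)
```

## The design being modeled

A case strain (the diabetic GK rat) and a control strain (WKY) are
sampled cross-sectionally at five ages — 4, 8, 12, 16 and 20 weeks —
with six animals per strain per age. Five of the six animals in each
group are assayed on Affymetrix 230-2 arrays (31,099 probe sets, up to
11 PM/MM probe pairs each), giving 25 chips per strain; all six
contribute physiology (body and fat-pad weights, food intake, HbA1c,
hormones, leukocyte counts, plasma lipids). Animals are terminal at
their sampling age, so age is a between-subjects factor: nothing here is
a repeated-measures model, and the package deliberately offers none.

## Detection calls

A probe set's evidence of expression on one chip is carried by its probe
pairs' discrimination scores $s_i = (PM_i - MM_i)/(PM_i + MM_i)$. Pairs
with $PM_i + MM_i = 0$ carry no information and are dropped (and
counted). The scores are tested against a small offset $\tau$ with a
one-sided Wilcoxon signed-rank test of $H_0\!: \mathrm{median}(s - \tau)
= 0$ versus $>$; the p-value is cut at $\alpha_1$ (Present) and
$\alpha_2$ (Marginal).

Parameter defaults — $\tau = 0.015$, $\alpha_1 = 0.04$, $\alpha_2 =
0.06$, all dimensionless and configurable — are the vendor defaults of
the MAS5 detection algorithm, which the emulated analysis used
implicitly; the original report names only the P/M/A output.

Numerical policy for the test itself:

* scores exactly equal to $\tau$ are dropped before ranking (zero
  differences carry no sign); if all are dropped the test is degenerate
  and returns $p = 1$ with a flag;
* ties in $|s - \tau|$ receive midranks, and the null distribution is
  the *conditional* one given those midranks, enumerated exactly over
  all $2^n$ sign assignments through a generating-function convolution
  on doubled ranks (midranks are half-integers, so doubling makes them
  integers); a cached table serves the common tie-free case;
* the exact path is used up to $n = 25$ remaining scores. The 230-2
  arrays have at most 11 pairs per probe set, so real input always takes
  the exact path; beyond 25 a normal approximation with continuity and
  tie correction takes over.
* saturation masking of MM-saturated pairs is deliberately not
  implemented: the generator never saturates, and signals are taken as
  given (no CEL parsing, no background correction, no signal
  summarization).

Because the scores are ratios, the whole chain — scores, p-values, calls
— is invariant to a common rescaling of PM and MM, which is why the
order of call generation relative to per-chip normalization is
immaterial.

## The screening cascade

1. **Per-chip percentile scaling.** Every chip is divided by the 50th
   percentile (linear interpolation, `stats::quantile` type 7) of its
   *strictly positive* signals. Zeros are excluded so chips with many
   unexpressed probe sets are not dragged toward zero; a chip with no
   positive signal is an error, named. The operation is idempotent and
   brings each chip's positive-value median to 1.
2. **Expression filter.** A probe set is expressed if it is Present on
   at least $m$ chips (default 5) of the case strain *or* of the control
   strain, out of $N = 25$ each. The union ("either strain") reading is
   the default because the screen's purpose is to keep any transcript
   expressed in the tissue of either strain; the intersection rule and a
   switch counting Marginal as Present are exposed for sensitivity
   analysis.
3. **Control-median ratio normalization.** Every value of probe set $i$
   is divided by the median of probe set $i$ over *all* control chips
   (global, not age-matched — the per-age comparison happens in the next
   step, where a global reference cancels anyway). This is a display
   convenience: the package proves, and the tests assert numerically,
   that between-group fold ratios are identical before and after this
   division — except for probe sets whose control median is exactly
   zero, which are floored at $\varepsilon = 0.01$ and flagged, and for
   which no fold identity holds.
4. **Per-age folds and persistence.** fold$(i, a)$ = case-group median /
   control-group median at age $a$ (5 vs 5 chips; medians for
   consistency with every other summary in the cascade, means by
   config). A probe set survives if fold $\ge f$ (default 2) at $\ge k$
   ages (default 3 of 5), or fold $\le 1/f$ at $\ge k$ ages. Direction
   must be consistent: the up- and down-counts are kept separately, so
   with $k \ge 3$ of 5 ages the two directions are mutually exclusive
   and the survivor count always equals case-higher + control-higher.
   With $k \le 2$ both directions can qualify; the package then warns
   and assigns the side with more qualifying ages.

The screen is threshold-based by design — it produces no p-values, so
there is nothing to correct for multiple testing; it *eliminates* probe
sets that fail criteria rather than selecting winners.

## Rollup, categories, overlap

Survivor probe sets collapse to genes through a static annotation table
(probe set → symbol + one primary functional category; multi-label
annotation is not supported). The report counts unmapped probe sets
(symbol `UNMAPPED`, category EST), mapped probe sets, distinct genes,
and duplicate instances = mapped − distinct, with the invariants
`n_probe_sets = n_unmapped + n_mapped` and `n_genes = n_mapped −
n_duplicate_instances`. Sequence-level identification (BLAST against
current databases) is out of scope: it is database-version-dependent,
and category tallies depend on curation judgment, so the package
reproduces them as counts *given a map* and never asserts particular
values. Cross-tissue comparison is a plain set intersection of survivor
ids.

## Physiology statistics

Derived variables are per-animal ratios (e.g. food intake per gram body
weight, g/day/g; fat pad as a fraction of body weight, g/g); rows with a
missing or zero denominator are skipped and counted. HbA1c is censored
at its assay's lower limit of detection, 4%: values below are set to the
floor and flagged.

The inferential tool is the rank-transform factorial ANOVA: all
observations of one variable (60 at full design) are replaced by global
midranks, a two-factor fixed-effects ANOVA (strain, age, strain × age)
is fitted to the ranks with `stats::aov`, and Tukey's HSD
(`stats::TukeyHSD`) is applied to all 10 strain × age cell means — the
studentized-range critical value therefore accounts for the full 45-pair
family — but only the five same-age strain contrasts are *reported* as
flags, at 0.05 and 0.001, mirroring the per-age one- and two-asterisk
annotations of longitudinal figures. The full pairwise table is returned
for inspection. Global ranking is the standard rank-transform ANOVA and
the default; ranking within age is available by argument. Because ranks
are invariant under strictly monotone maps, so is the entire result — a
property the tests assert directly. Flag direction is taken from the
sign of the raw cell-median difference, so it too survives monotone
transforms.

Design choices made where the procedure was genuinely open: whether the
original post-hoc compared only within-age pairs or all 45 cannot be
recovered from published figures; flagging per age matches how such
figures are annotated, and the wider Tukey family makes the flags
conservative. The null calibration (equal strain trajectories, 1,000
seeded replicates) bounds the per-age flag rate at the 0.05 level by
0.07 — generous headroom over the family-wise control, allowing for rank
discreteness with $n = 6$ per cell.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions: 2 strains × 5 ages × 5 chips per group, 11 pairs per probe
set, 6 animals per strain-age group, 30% absent probe sets, 4% of
expressed probe sets differential, a point-mass 4-fold effect, and
log2-scale noise sd 0.3.

Expression model: expressed probe sets draw a baseline log2 intensity
from $N(7, 1)$ (arbitrary fluorescence units; bright enough that
expressed probes are reliably Present, with a dim tail); $PM =
(\text{signal} + b)\,2^{\epsilon}$ and $MM = b\,2^{\epsilon'}$ with
cross-hybridization background $b = 30$ and iid noise $\epsilon \sim
N(0, 0.3)$; absent probe sets emit background in both channels, so their
scores straddle zero and they are called Absent (with the realistic
exception of occasional noise-driven Present calls). The summarized
signal matrix uses a smaller additive floor (10) so absent probe sets
have a small positive signal. Differential probe sets have their
case-strain signal multiplied or divided by the true fold in the ages of
a configurable window — included precisely because effects confined to
2, 3 or 5 of the ages exercise the $k$-of-5 rule on both sides. A
per-chip scale drift $2^{N(0,\,0.2)}$ emulates chip brightness
differences and is exactly what the percentile scaling removes. All
generation is deterministic given a mandatory seed.

Physiology model: per-animal values are strain × age cell means plus
Gaussian noise with per-variable sds, truncated at zero. The triglyceride
cell means are the study's printed per-age values; the other
trajectories reproduce the published shapes qualitatively — body weight
diverging from 8 weeks, case fat pads plateauing at 12 weeks and
easing after 16, HbA1c rising from the 4% floor to ~11.5%, control
corticosterone flat near 122 ng/ml against a declining case curve,
leptin tracking fat mass in controls but disproportionately high in the
case strain, case leukocytes elevated at every age. A `null_strain`
switch copies the control trajectories to both strains for calibration
runs.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real arrays: probe-sequence affinity differences,
MM saturation, spatial artifacts, batch structure beyond a scalar chip
drift, correlated noise across probe sets, circadian sampling-time
effects on hormones, and non-lognormal heavy tails. Tests against the
generator verify the *pipeline's logic and contracts* (recovery of
planted truth, invariances, count conservation), not field performance
on deposited data.

## Problem sizes and runtime choices

The test suite and the acceptance script run the cascade at 1,000–5,000
probe sets rather than the full 31,099: every operation is
probe-set-wise, so counts scale linearly and no logic depends on the
matrix height; these sizes keep a full verification run in minutes while
still pooling hundreds of planted effects (the acceptance run pools ~280
planted and ~9,700 null probe sets over ten seeds) and 1,000 null
ANOVA replicates. The exact signed-rank path is $O(n^2 \sqrt{n})$-cheap
at $n \le 11$ and cached for the tie-free case, so detection on 250,000
probe-set × chip cells is the budget item, not the statistics.

## Known limitations

* Real GEO deposits' processed tables carry signals but not probe-level
  PM/MM, so detection calls must either accompany the deposit (as a
  P/M/A matrix read with `read_signal_matrix`) or be computed upstream;
  they cannot be recomputed from the signal matrix alone.
* The ε-floor for zero control medians makes flagged probe sets'
  ratios scale-dependent; they are reported but should not be
  interpreted as folds.
* The annotation rollup resolves each probe set to a single primary
  category; genes that straddle categories are represented once.
* With fewer than 2 observations per strain × age cell the rank ANOVA
  refuses to fit rather than degrading to an unbalanced approximation.
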