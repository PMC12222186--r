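---
title: "Methods: cross-setting dose-response meta-analysis of salt-stress studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-setting dose-response meta-analysis of salt-stress studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmeta)
```

## The problem

Published salt-stress experiments on a crop are run in very different
environments — open fields on saline soil, pots standing outdoors, pots in a
greenhouse, pots in a climate-controlled chamber — and there is accumulating
evidence that the apparent severity of a stress depends on the setting as
much as on the stress itself. `saltmeta` implements a pipeline for asking,
from a corpus of study-level summary data, *whether plants in different
experimental settings respond differently to the same salinity dose*.

Each corpus row is one published observation: control and stress treatment
means of one variable (yield, biomass, height, ion or metabolite content)
at one salinity level, with the salinity of both treatments, the setting,
the developmental stage and the stress duration as metadata.

## Normalization

Three derived quantities put heterogeneous studies on a common scale:

* **EC conversion.** Salinity reported as molar NaCl or ppm NaCl is
  converted to electrical conductivity with the linear factors
  98 dS/m per 1 M NaCl and 1.66 dS/m per 1000 ppm NaCl. Linearity over the
  agronomically relevant range is a deliberate simplification; NaCl
  solutions are close to linear in EC at these concentrations.
* **Relative EC** = stress EC − control EC. Studies report either soil
  salinity or the salinity of the irrigation solution, usually with no
  baseline for the control; subtracting the control EC sets every control
  to zero and makes the stress axes comparable. Relative EC is invariant
  under a common shift of both salinities, which the test suite checks as a
  property.
* **Relative response** = stress mean / control mean. A ratio of 1 means no
  effect; below 1 a stress-induced decrease. Ratios are invariant under
  rescaling of the measurement units, also checked as a property.

For growth variables measured at the **vegetative stage** the duration of
exposure modulates the response, so their stress axis is the **stress
integral** — relative EC × stress duration (dS·day/m) — instead of relative
EC. Duration is taken to run from stress onset to measurement unless the
record says the salt was flushed.

Replicate rows (several genotypes, repeated years) are collapsed by an
unweighted arithmetic mean before any effect is derived; the row
granularity analyzed afterwards is the aggregated one, and the
effective-stress gate below is applied *after* aggregation, matching that
granularity. Fresh-weight metabolite concentrations are ingested but
flagged out of the analysis, because dry-weight and fresh-weight bases are
not comparable under salt stress (osmotic water loss changes fresh weight
itself). Finally, whole salinity levels are dropped when neither shoot dry
weight nor grain yield decreased (ratio < 1): levels with no effective
stress carry no dose-response information. Levels lacking both anchor
variables are kept with a warning by default — a corpus collected under
this design guarantees at least one anchor — and a `policy = "drop"` switch
exists for stricter use.

## Binning and outlier control

Pairwise tests between settings compare pooled relative responses, which is
only fair if the two settings are compared *at the same doses*. The stress
axis of each variable is therefore partitioned into bins under two
constraints: every covered setting must contribute at least `min_count`
observations (default 5) to every bin, and the per-setting mean axis values
within a bin should be as close as possible. The search formalizes the
second requirement as minimizing `J`, the worst-bin spread (max − min
across settings) of within-bin mean axis values, over candidate edge
sequences seeded from pooled quantiles at every feasible bin count and
greedily merged until the count constraint holds. Ties prefer fewer bins,
then lexicographically smaller edges, so the scheme is deterministic.
Settings that cannot reach `min_count` even in a single full-range bin are
dropped from coverage with a warning. Because such schemes were
historically chosen by hand, explicit user-supplied edges always override
the search. Bins are half-open `[lo, hi)` with the last bin closed — the
standard histogram convention, stated here because nothing upstream forces
it.

Within each (bin, setting) cell a **single-pass Hampel filter** removes
gross outliers: values farther than `k = 3` scaled median absolute
deviations from the cell median are excluded, with median and MAD computed
once on the full cell (no iteration). Two scalings are first-class:
`scale = 1.4826` (default), under which the MAD estimates a Gaussian
standard deviation — the usual Hampel-filter convention — and `scale = 1`,
the literal "three median absolute deviations" reading; reports record
which was used. When the MAD is zero (at least half the cell identical)
nothing is excluded: the literal rule would discard every non-median point,
which is clearly not the intent of an outlier filter.

## Pairwise setting comparisons

For each unordered pair of covered settings, retained responses are pooled
across the bins where both settings have data, and a two-sample test is
chosen by a gated decision tree:

1. Shapiro–Wilk on each group of the raw data; if both pass
   (p > 0.05) the candidate scale is raw. Otherwise Shapiro–Wilk on the
   log data (only if strictly positive); if both pass, the candidate scale
   is log.
2. Brown–Forsythe (median-centered Levene) variance homogeneity on the
   candidate scale; if it passes, a **permutation t-test** on that scale;
   any failure falls through to the **Mann–Whitney U test** on raw data.

Both tests are implemented from first principles. The permutation test uses
the pooled-variance Student t statistic — permutation inference assumes
exchangeability, i.e. equal spread, which the variance gate has just
checked — and enumerates all label assignments exhaustively when
`choose(n, n_a)` ≤ 10,000; otherwise it samples `B` permutations (default
9,999) and reports the add-one estimate `(1 + hits) / (1 + B)`, which can
never be zero. The Mann–Whitney test counts
`U = #{a_i > b_j} + ½·#{ties}`, with an exact enumeration p for tie-free
samples and a tie-corrected, continuity-corrected normal approximation
otherwise. The normality gate is applied per group (both groups must pass)
rather than pooled, and the homogeneity test is Brown–Forsythe for its
robustness to non-normality; both are configurable because neither choice
is forced by the procedure being emulated. p-values are reported without
multiplicity correction, matching common figure-level reporting of such
comparisons; a Holm option exists.

## The factorial arm

Designed experiments crossing stress (control/salt) with setting are
analyzed by a two-way ANOVA with interaction, using type-II sums of squares
so unbalanced designs (lost plants) are handled sensibly; on balanced
designs these equal the classical decomposition and sum exactly to the
total sum of squares (a test asserts this to 1e-12). If a Shapiro–Wilk
test finds the ANOVA residuals non-normal (p ≤ 0.05) the ANOVA is replaced
by the **Scheirer–Ray–Hare** rank test: mid-rank the response, decompose
the rank sums of squares, and refer `H = SS_effect / MS_total` (with
`MS_total = SS_total/(N − 1)`, which deflates under mid-ranked ties —
exactly the standard tie correction) to a chi-square with the effect's
degrees of freedom. Rank invariance under strictly monotone response
transforms is asserted in the tests.

## The synthetic corpus generator

Tests and calibration experiments run on synthetic corpora whose structure
mirrors the assumptions above. The per-setting mean response follows a
modified discount curve `r(x) = 1 / (1 + (x / c50)^shape)` — the classical
sigmoidal salt-tolerance form, equal to 1 at zero added salinity and 0.5 at
`x = c50`; any strictly decreasing family with `r(0) = 1` would serve, and
the form is exposed as a plain function so tests do not over-fit to it.
Defaults encode the emulated study conditions:

* field `c50 = 30`, outdoor pots `20`, greenhouse `12`, climate chamber
  `10` dS/m (field plants least affected), `shape = 1.5`;
* multiplicative lognormal noise, `sigma = 0.25` on the log scale — the
  between-study spread of response ratios;
* 5% contamination by gross outliers (×4 or ÷4), the targets of the Hampel
  filter;
* study counts `15 : 10 : 37 : 6`, the published corpus composition
  `117 : 77 : 296 : 49` scaled by ~1/8 so imbalance is exercised at test
  scale;
* three salinity levels per study with relative EC uniform on 2–30 dS/m,
  control salinities on 0–2 dS/m, durations 14–60 days; a fifth of studies
  report salinity in molar or ppm units so unit conversion is exercised
  end to end.

For vegetative-stage variables the response is driven by the stress
integral, with the EC-scale `c50` mapped onto the integral scale by a
reference duration of 30 days. Within a study the control baseline cancels
out of the ratio, so generated ratios are independent across levels — the
generator does not emulate within-study correlation of response ratios,
shared-control dependence, publication bias, or heteroscedasticity across
the dose range; passing calibration here shows the pipeline's tests are
valid under independence, not under those violations.

## Calibration and recovery experiments

Two Monte-Carlo properties tie the whole pipeline together, run both in
the test suite and by `scripts/acceptance.R`:

* **Type-I calibration.** 500 corpora generated under a null configuration
  (all four settings share `c50 = 15` and all other parameters), one
  variable (grain yield), full pipeline, `B = 999` permutations; the
  fraction of pairwise comparisons rejecting at α = 0.05 measures the
  pipeline's actual size. One variable and `B = 999` are the chosen
  experiment size; the rejection-rate granularity of 999 permutations is
  ample at α = 0.05. A caveat worth knowing: filtering each
  (bin, setting) cell *separately* before pooling — which is what the
  procedure prescribes — self-normalizes each group and makes the
  downstream tests slightly liberal when gross contamination is present.
  The same experiment with the filter disabled is calibrated almost
  exactly at the nominal level, and the inflation reproduces with
  textbook tests on hand-trimmed samples, so it is a property of the
  trim-then-test design rather than of this implementation. At the
  default 5% contamination the measured size typically lands a point or
  two above the nominal 5%; users who need strict size control should
  disable the filter or interpret borderline p-values accordingly.
* **Recovery.** 200 corpora under the default (alternative) configuration;
  the field-vs-greenhouse grain-yield comparison must reject in ≥ 80% of
  corpora, and the pooled binned field mean must exceed the greenhouse
  mean in ≥ 95% — i.e. the pipeline recovers both the existence and the
  direction of the generated setting difference (field least affected).

## Numerical choices and limitations

Degenerate inputs are handled explicitly: zero pooled variance with equal
means gives t = 0 and p = 1; a permutation p can never be 0 by the add-one
convention; a MAD of zero excludes nothing; a constant factorial response
is reported as degenerate rather than erroring; an all-tied rank response
likewise. Axis values exactly on an interior bin edge go to the upper bin;
the last edge belongs to the last bin. Every stochastic step takes an
explicit seed and restores the caller's RNG state, and the analysis
manifest records parameters, seed and every filtering decision count, so
any reported number is reproducible from the manifest alone.

The pipeline pools unweighted study means: no meta-regression, no
random-effects weighting by study precision, no dose-response curve
fitting to the binned means, and no correction for the fact that several
ratios can share one published control. Those are analysis-design limits
of the emulated procedure, not implementation shortcuts.
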