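---
title: "Fragility analysis of two-arm trials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility analysis of two-arm trials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rctfragility)
```

## The model

A significant dichotomous trial result is summarized by a 2×2 table: arm
(intervention/control) by outcome (event/non-event). Conditioning on both
margins, the event count in the intervention arm follows a hypergeometric
distribution under the null of no association, and the two-sided Fisher
exact p-value is the sum of the point probabilities of every
margin-preserving table no more probable than the observed one (the
*minimum-likelihood* rule).

The fragility index iterates a single deterministic move: in the arm with
the fewer events (fixed once, from the original table), one patient's
outcome is reclassified from non-event to event. Arm sizes and the total
randomized N are invariant under the move. The FI is the smallest number
of moves after which the recomputed exact p reaches or exceeds the
significance threshold α (default 0.05, configurable everywhere). The
fragility quotient divides FI by N.

Assumptions worth stating explicitly:

* The analysis treats the published 2×2 counts as the analysis population;
  it does not reconstruct intention-to-treat discrepancies.
* The exact test is the arbiter of significance during the iteration even
  when the original trial used another test. A trial can therefore have
  FI = 0: its own test was significant but the exact test is not at α.
  This is a real phenomenon in extracted corpora, not an error state.
* Only 1:1 two-arm designs with dichotomous outcomes are in scope; each
  corpus row carries one pre-selected outcome. For trials reporting
  several significant outcomes the convention is to analyze the
  outcome with the smallest FI; `min_fragility_outcome()` performs that
  selection when candidate tables are available.

## Two-sided convention and numerical choices

The "two-sided Fisher test" admits several conventions. The package fixes
the minimum-likelihood rule because it is the one implemented by
mainstream exact-test software and the popular online fragility
calculators, which makes results comparable with published fragility
analyses. Mid-p variants, one-sided tests, and chi-square approximations
are deliberately out of scope: fragility flips hinge on the exact position
of p relative to α, so the kernel is always a full enumeration of the
conditional support via log binomial coefficients.

Two numerical guards matter at this boundary:

* **Tie tolerance.** A table counts as "at most as probable" as the
  observed one if its pmf is ≤ observed·(1 + 1e−7). Point probabilities
  that are mathematically equal can differ in floating point depending on
  the order of accumulation; without the tolerance a tied extreme table
  can silently drop out of the two-sided sum.
* **α-boundary guard.** Exact p-values are rationals and can equal α
  exactly (for example 30/600 = 0.05). `fragility_index()` treats
  p ≥ α − 1e−12 as non-significant so that rounding noise of order 1e−16
  cannot flip the p ≥ α decision. Mathematically, p = α is
  non-significant under the "smallest k with p ≥ α" definition, and the
  guard makes the implementation agree with that statement bit-for-bit
  across independent evaluation routes. Distinct achievable p-values near
  0.05 are separated by far more than 1e−12 for any realistic table size,
  so the guard cannot merge genuinely different outcomes.

Other decisions in the iteration:

* **Tied event counts.** The procedure's "arm with fewer events" is
  undefined when the counts tie. Both directions are evaluated and the
  smaller resulting index is returned, consistent with reading the FI as
  a minimum over either group; the result records which arm achieved it.
* **Exhaustion.** If the modifiable arm runs out of non-events while the
  table is still significant, the result is flagged `exhausted` rather
  than raising an error; `fi` then records the number of non-events
  consumed. Cohort summaries exclude exhausted records and say so — a
  median over values with a censored upper bound would be misleading if
  the exhausted value were kept as-is.

## Corpus conventions

* **Year bins.** Publication years partition into before 2000, 2000–2010,
  and 2011-present. The boundary year 2010 belongs to the middle bin:
  the "present era" bin is the set of trials published after 2010.
* **Journal groups.** Five named journals (New England Journal of
  Medicine, Journal of Pediatrics, Neonatology, Pediatrics, JAMA) are
  matched case-insensitively and exactly; everything else is `Other`.
  Fuzzy matching is deliberately avoided — extraction pipelines should
  normalize names, not the analysis.
* **Tri-state design flags** (multicenter, double-blinded, registered)
  collapse to *yes* versus *no-or-unsure* in the subgroup table, because
  "not reported" is epistemically closer to "no" than to "yes" in
  published trial reports, and two groups keep the comparison a U test.
* **Quantiles.** All medians and IQRs interpolate order statistics at
  h = (n−1)p + 1 (type-7). This is the dominant default across
  statistical environments and produces the familiar half-integer medians
  (e.g. 2.50, 149.5) from even-sized samples.
* **Rank tests.** Two occupied groups are compared with the Mann–Whitney
  U test: exact enumeration when both groups have ≤ 8 observations and no
  ties, otherwise the tie-corrected normal approximation with a 0.5
  continuity correction. Three or more occupied groups use the
  tie-corrected Kruskal–Wallis H against the chi-square upper tail. The
  choice is made on *occupied* levels: an empty level is reported with a
  zero count but cannot participate in a test.
* **Sparse subgroups.** A subgroup with fewer than 4 trials reports its
  median but `NA` quartiles — quartiles interpolated from 1–3 points are
  noise presented as precision.
* **Multiple testing.** None is applied across the subgroup table; raw
  per-characteristic p-values mirror standard practice in fragility
  meta-research, and the documentation says so rather than hiding it.
* **Missing reported p-values.** The correlation panel against reported p
  drops incomplete pairs pairwise and reports the count; a panel with
  fewer than 3 usable pairs is omitted with a warning.
* **Spearman correlations** are computed as the Pearson correlation of
  joint mid-ranks, with the two-sided p from the t approximation on
  n − 2 degrees of freedom. Under heavy ties this is the defensible
  definition (the classical 1 − 6ΣS/(n³−n) formula is biased by ties).

## The synthetic corpus generator

There is no public machine-readable corpus of this kind of hand-extracted
trial table, so the generator exists to make every downstream stage
testable and to support simulation studies. It emulates the *selection
process* that produces such corpora: two-arm 1:1 binomial trials, drawn
from plausible size and effect distributions, kept only if the analyzed
outcome is statistically significant.

Per trial: a shared arm size n ~ round(LogNormal(μ = 4.45, σ = 1.1)),
floored at 5 — the raw draw has a median total N near 170 and quartiles
roughly 80–370, the size range typical of neonatal RCTs; a control-arm
risk p₀ ~ U(0.1, 0.5), spanning common neonatal endpoint rates
(mortality, bronchopulmonary dysplasia, sepsis); a risk ratio
r ~ U(0.3, 0.8) for a beneficial intervention; event counts binomial per
arm; rejection until the two-sided exact p < α, with a configurable
redraw budget so a hopeless configuration fails loudly instead of
spinning. Losses to follow-up are Binomial(2n, rate) with
rate ~ U(0, 0.1). Publication metadata (year, journal group, design
flags) is drawn categorically with frequencies typical of a neonatal
trial literature sample and never feeds back into the counts. These
defaults were fixed once, on face validity, and are fully exposed in
`simulation_config()` so studies can pin their own.

Reproducibility: the root seed yields one substream seed per trial, so a
given (config, seed) pair always produces a byte-identical corpus CSV and
enlarging a corpus never reshuffles its earlier trials.

Two structural features of real corpora the generator does *not*
reproduce, and what that means for interpretation:

* **Selection on the trial's own test.** Filtering on the exact Fisher
  test guarantees FI ≥ 1 for every synthetic trial. Real corpora contain
  FI = 0 trials because the original analyses used chi-square or other
  tests. The `reported_test = "chi_square"` mode filters on an
  uncorrected chi-square p instead, which regenerates the FI = 0
  phenomenon; it is a mode, not the default, because the exact-filter
  corpus is the cleaner test fixture.
* **Size bias of the filter.** Rejection sampling accepts under-powered
  small trials rarely, so the accepted size distribution sits above the
  raw log-normal draw. This mirrors a real selection effect
  (significant results are easier to obtain in larger trials given
  moderate effects) but means the accepted-corpus median N is not the
  raw draw median.

Consequently, passing tests on synthetic corpora demonstrate that the
pipeline's statistics recover the structure the generator put in — e.g.
the direction triple (FI rises with sample size and total events, falls
with reported p) — not that any particular published corpus is
reproduced.

## Verification design

The test suite checks each layer against an independent route:

* the exact test against a full-enumeration oracle built on `dhyper`,
  over every 2×2 table with N ≤ 60 (tolerance 1e−12), plus spot
  agreement with `stats::fisher.test`;
* the FI iteration against a naive oracle that rebuilds every modified
  table explicitly and retests, over the complete grid of arm sizes
  ≤ 20 — a grid chosen because it contains thousands of FI = 0 tables
  and all the exhaustion corner cases while enumerable in seconds;
* the rank tests against 10,000-draw permutation oracles on tied and
  untied samples, and Spearman against a hand-written rank-then-Pearson
  computation at 1e−12;
* the generator's direction triple on a seeded 500-trial corpus — large
  enough that the Spearman signs are far from zero with margin, small
  enough to run in seconds.

## Limitations

* Continuous-outcome fragility is out of scope; so are cluster
  randomization, non-1:1 allocation, and reverse fragility for
  non-significant results.
* There is no accepted threshold separating "fragile" from "robust"; FI
  and FQ are comparative metrics, and the package reports them without a
  verdict.
* FI computed on secondary outcomes inherits the usual caveat that the
  trial was not powered for them.
* The subgroup table's p-values are descriptive; with eight
  characteristics tested without correction, isolated small p-values are
  expected under the null.
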