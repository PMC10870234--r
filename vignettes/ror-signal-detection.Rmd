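---
title: "Reporting odds ratio signal detection on FAERS quarterly data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio signal detection on FAERS quarterly data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) accumulate millions of Individual Case Safety
Reports. Because there is no denominator of exposed patients,
pharmacovigilance works with *disproportionality*: is an event reported
with a given drug more often than the reporting background would predict?
`faersror` implements that workflow end to end for the public FAERS
quarterly ASCII archives, with the 2020–2022 COVID-era analysis of
remdesivir and tocilizumab — and in particular their pregnancy-, foetus-
and neonate-related signals — as the motivating application.

## The statistic

For a study drug $P$ and an event Preferred Term $R$, reports are
cross-classified at report level:

|            | event $R$ | all other events |
|------------|-----------|------------------|
| drug $P$   | $a$       | $b$              |
| all others | $c$       | $d$              |

The Reporting Odds Ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d},$$

with the Wald 95% confidence interval on the log scale,

$$\exp\!\left(\ln \mathrm{ROR} \pm 1.96\,
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

The CI formula is the standard Wald interval used throughout ROR-based
pharmacovigilance; the interval method is a package choice, since "95% CI"
alone does not pin one down. A drug–event pair is flagged as a **potential
safety signal** when the pair frequency satisfies $a \ge 3$ and the lower
CI bound strictly exceeds 1. Two degenerate cases are kept distinct:

* $c = 0$ (the event is reported for no other medicine): the ROR is
  incomputable and the conventional sentinel value **99.9** is assigned,
  with no CI; a sentinel pair with $a \ge 3$ counts as a signal.
* $a = 0$, $b = 0$ or $d = 0$ with $c > 0$: the estimate is flagged
  non-computable and is never a signal. No continuity correction is
  applied anywhere — inventing half-counts would silently manufacture
  evidence, and the sentinel stays reserved for the $c = 0$ convention.

Pairs with $a \ge 5$ carry a separate flag, since signal lists are often
read at that stricter frequency. No multiple-testing adjustment is applied;
the scan is a hypothesis-generating screen, not a confirmatory analysis,
and every pair's full $(a, b, c, d)$ is emitted so readers can apply their
own corrections.

## Curation decisions

**Deduplication.** FAERS re-files updated cases under the same `caseid`
with a higher `caseversion`, so only the most recent version of a case is
kept. "Most recent" is implemented as the lexicographic maximum of
(`caseversion`, FDA receipt date, `primaryid`): the version number is the
authoritative ordering, and the two tie-breaks make the result
deterministic when versions collide. Deduplication runs on the union of
all quarters *before* any drug filtering, and identifiers are compared as
strings (leading zeros preserved). Only the identifier key is used —
probabilistic duplicate detection on demographics is deliberately out of
scope.

**Event-date window.** Reports are excluded when their event date lies
wholly outside the inclusive window (2020-01-01 to 2022-12-31 in the
motivating analysis). FAERS dates can be partial (year or year-month); a
partial date is excluded only when *no completion* of it can fall inside
the window, and reports with no event date at all are kept, because an
exclusion rule phrased around the event date presupposes one. The same
rule applies symmetrically at both window ends.

**Drug matching.** A report belongs to the study drug when one of its drug
records carries a role in the query's role filter (default: primary
suspect only, which trades sensitivity for specificity in signal
generation) and its verbatim product name *or* active-ingredient string
matches a query name — INN or brand — case-insensitively as a whole-word
token. Token matching accepts `"REMDESIVIR/XYZ COMBO"` while rejecting
matches buried inside longer words; free substring search and fuzzy
normalization are both rejected as silent scope changes.

**Comparator universe.** Whether reports that carry the study drug in a
*non*-primary role belong in the comparator cells is genuinely ambiguous
in standard practice. The default counts every report not selected by the
query (the cells then partition the dataset exactly); the alternative,
`comparator = "exclude_any_role"`, removes such reports from the universe
entirely. Both are first-class options so the sensitivity of a signal list
to this choice can be measured.

**SOC mapping.** MedDRA is licensed, so System Organ Class aggregation
takes a user-supplied flat PT-to-SOC table. Lookups are case-insensitive;
unmapped PTs group under "Unmapped" with a warning and are never guessed.
The bundled `soc_map_synthetic.tsv` covers only the terms used by the
package's own fixtures and generator.

**Rendered tables.** Percentages and rendered ROR/CI columns use half-up
rounding to one decimal, the convention of published signal tables; full
precision is kept internally.

## The synthetic generator

Because the real archives are multi-gigabyte downloads, the package
carries a generator that emits the same ASCII dialect the reader consumes,
with ground truth known by construction:

* One primary-suspect drug per report, drawn directly from the drug
  vocabulary's marginal probabilities; additional drug records join
  independently with secondary-suspect/concomitant/interacting roles.
  Drawing the PS drug directly (rather than picking one of several
  sampled drugs) keeps $\Pr(\text{PS} = g)$ exactly the configured
  marginal, which the expected contingency cells rely on.
* Event terms enter a report independently with background probability
  $p$, i.e. odds $o = p/(1-p)$. An injected pair $(g, e, \lambda)$
  multiplies $e$'s *odds* by $\lambda$ in reports where $g$ is the PS
  drug. The odds parameterization is what makes the population ROR of an
  injected pair equal $\lambda$ exactly, and no probability can be pushed
  past 1, so no configuration is infeasible.
* A report whose independent draws produce no event receives a dedicated
  filler term (`"Adverse event"`) outside the analysis vocabulary. This
  enforces the one-reaction minimum of real FAERS data without
  conditioning the vocabulary terms' draws, which would bias the realized
  ROR.
* Configured fractions of cases are re-filed at `caseversion` 2 with a
  later receipt date, dated outside the window, degraded to year-month
  date precision, or stripped of age/sex/occupation — so every curation
  rule is exercised by data that look like the real failure modes.
* Reports are i.i.d.: reporter-behavior correlations (underreporting,
  severity-dependent reporting, stimulated reporting waves) are *not*
  modeled, because no quantitative model of them is available to copy.
  Passing recovery tests therefore demonstrates correctness of the
  statistics under the stated model, not robustness to reporting biases
  in real data.

Default generator parameters (ten drugs; 24 event terms at 0.8–12%
background; 1.5 extra drug records per report; 5% duplicates; 2% out of
window; 15%/8%/3% missing age/sex/occupation) were chosen once as a
plausible small reporting universe and are fixed; tests and the acceptance
script run against these defaults.

## Verification strategy and problem sizes

* **Oracle equivalence**: contingency construction and the full signal
  scan are compared against a brute-force per-report classifier on random
  universes of up to 500 reports, and the closed-form ROR/CI against an
  independent logistic-regression route to the same estimand.
* **Hand-enumerated fixture**: a 44-row universe whose every tally —
  3 superseded versions, 1 out-of-window report, a 40-report universe,
  four scanned pairs straddling the frequency-3 and CI boundaries, the
  reporter/outcome/indication tables, a drilldown with 2 of 7 ages
  missing — was worked out by hand and frozen in `fixture_manifest()`.
* **Type-I calibration**: with nothing injected, the fraction of pairs
  with lower CI bound above 1 is checked against the nominal one-sided
  2.5% over 20 simulations of 2,000 reports.
* **Parameter recovery**: $\lambda \in \{2, 5, 10\}$ injected at 20,000
  reports; the pipeline CI covers $\lambda$ in at least 90% of 50 seeds.
* **Published arithmetic**: the percentage columns of the notifier and
  outcome tables are recomputed from the printed counts, and the printed
  pregnancy-related rows re-classified under the signal rule (six
  remdesivir signals, three tocilizumab signals).

These sizes keep the whole suite in the one-minute range on a single CPU
while leaving the Monte-Carlo error well inside the asserted slack.

## Limitations

* Full-archive counts (millions of reports, hundreds of signals) are not
  desk-scale reproducible and depend on the FDA's own file revisions; the
  pipeline instead narrates its curation tallies so a full-scale run can
  be compared against published flowchart numbers.
* The ROR is a reporting association, not a risk estimate; a signal is a
  hypothesis to be tested in proper epidemiological designs, never
  evidence of causation.
* Name matching is verbatim-token based; misspelled product names in real
  FAERS data will be missed unless added to the query list.
* The RPSR and THER tables of the FAERS archive are not modeled; no field
  of them enters this analysis.
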