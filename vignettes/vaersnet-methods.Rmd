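---
title: "Methods: disproportionality signals and association networks for spontaneous vaccine AE reports"
author: "vaersnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaersnet)
```

## The data model

A spontaneous vaccine-safety report, as distributed by VAERS-style passive
surveillance systems, is split across three CSV tables keyed by a report
identifier: general report data (receipt date, patient sex and age), one row
per administered vaccine, and one row per reported MedDRA-style symptom term.
`readReports()` joins the triplet into a `ReportSet`: one record per distinct
identifier in the Data table, with deduplicated vaccine and symptom *sets*
(a term listed twice in the raw file counts once). Reports with no vaccine or
no symptom rows are kept with empty sets: they contribute no pairs, but they
do count in the denominators of the reporting-ratio statistics, which are
defined over *all* reports in a stratum.

The reporting year is taken from the receipt date (`RECVDATE`, parsed as
MM/DD/YYYY), not the vaccination date, because yearly summaries of passive
surveillance activity conventionally group by when the system received the
report. Rows whose date fails to parse keep their report with a missing year
(they then appear in overall and sex strata but in no yearly stratum); the
ingestion tally reports how many. Sex codes are folded case-insensitively to
F/M, with everything else — including blanks — mapped to U. Reports of
unknown sex stay in the overall analysis and drop out of the sex-specific
strata only.

## Proportional reporting ratios

For a vaccine $V$ and symptom $S$ within a stratum (the whole corpus, one
reporting year $Y$, or one sex $G$), the proportional reporting ratio is

$$\mathrm{PRR}(V, S) = \frac{a/b}{c/d}$$

with $a$ = reports for $V$ containing $S$, $b$ = all reports for $V$, $c$ =
all reports containing $S$, and $d$ = all reports — each count restricted to
the stratum. Note the comparator here is the **entire stratum including
$V$'s own reports**, not the classic "all other vaccines" variant of the
statistic; a vaccine present in every report therefore has PRR exactly 1
against any symptom. This denominator convention is deliberate and is the
one the rest of the pipeline (significance filtering, network construction)
is calibrated against. When $b$, $c$ or $d$ is zero the ratio is undefined
and is carried as a flagged missing value (`NA`), never as 0 or infinity,
so undefined ratios can never pass a threshold test by accident.

A pair is *significant* when its stratum PRR is **strictly** greater than 1
(`significantAssociations()`, threshold configurable). No minimum-count or
chi-square companion criterion is applied: PRR > 1 is the sole filter, which
keeps the network construction transparent at the cost of admitting noisy
low-count pairs — a limitation users should keep in mind when interpreting
desk-scale runs.

Demographic summaries of the reports containing a pair use the standard
vaccine-surveillance age bins (<2, 2–17, 18–64, 65+, plus "unknown" for
missing ages; configurable), grouped by sex and reporting year.

## Association networks

The significant pairs of one stratum form a bipartite network: vaccine
nodes, adverse-event nodes, and one undirected edge per pair. Nodes exist
only through edges, so there are no isolates. Per stratum we report the
node and link counts, average node degree $2E/N$, average shortest-path
length and diameter. Shortest paths are unweighted breadth-first-search
distances on the undirected graph (computed via igraph); the average is
taken over unordered pairs of distinct, mutually reachable nodes and the
diameter is the largest finite eccentricity — the usual network-analyzer
convention for disconnected graphs, which the test-suite verifies against an
independent Floyd–Warshall implementation. On an undirected graph,
ordered-pair averaging would give identical values (also asserted in the
tests). Tabular output rounds half-up to two decimals; full precision stays
available on the `NetworkMetrics` object.

## Vaccine similarity, clustering and cross-sex comparison

To compare vaccines by their adverse-event repertoires the bipartite network
is projected with a Pearson association index: for same-type nodes $A, B$
with neighbour sets $N(A), N(B)$ in a network with $n_y$ opposite-type
nodes,

$$\mathrm{PCC}_{AB} = \frac{|N(A)\cap N(B)|\, n_y - |N(A)||N(B)|}
{\sqrt{|N(A)||N(B)|\,(n_y-|N(A)|)(n_y-|N(B)|)}}$$

which is algebraically the Pearson correlation of the two binary incidence
vectors over the $n_y$ opposite-type nodes: 1 means identical neighbour
sets, 0 chance-level sharing, −1 perfect complementarity. The index is
undefined when a degree is 0 or $n_y$ (a constant incidence vector); those
entries are carried as `NA` in the `SimilarityMatrix`.

Vaccines are clustered agglomeratively on the distance $1 - \mathrm{PCC}$
with average linkage. The linkage and distance are a design choice — the
source of this analysis style leaves them to the clustering tool — and
average linkage on a correlation-derived distance is the standard option for
profile clustering; both are configurable. Undefined entries are imputed as
0 (the chance reference point of the index) with a warning. Labels are
sorted lexicographically before clustering so ties in merge heights resolve
identically regardless of input order; permuting the input yields an
isomorphic tree.

The sex comparison builds the female and male networks from the
**sex-specific** PRR>1 edges (PRR recomputed within each sex stratum), not
by subsetting the overall network; restricting to vaccines present in both
strata, it pairs the off-diagonal index values, bins each side with a fixed
bin width of 0.05 over $[-1, 1]$ (so the two histograms overlay directly),
and reports the two-sample Kolmogorov–Smirnov distance as a purely
descriptive summary of distributional difference. No p-value is attached:
the off-diagonal entries of a similarity matrix are not independent
observations, so a KS test's sampling theory does not apply.

## RDF export

Association summaries serialize to RDF under a small project vocabulary
(`http://vaersnet.org/ns/`, prefix `vaers:`): one association resource per
pair with a deterministic identifier (percent-encoded vaccine code joined to
a 32-bit FNV-1a hash of the symptom term), linked to vaccine and symptom
resources via `vaers:hasVaccine` / `vaers:hasSymptom`, carrying
`vaers:reportCount` and `vaers:hasPRR` (or an explicit
`vaers:prrUndefined` marker — undefined ratios stay distinguishable from
any number). Yearly and sex strata are reified nodes with `vaers:forYear` /
`vaers:forSex`, a stratum count and a stratum PRR: 7 base triples per record
plus 4 per stratum node. Numeric literals are written with 17 significant
digits so doubles round-trip exactly. The writer emits Turtle or canonical
(sorted) N-Triples; the bundled reader parses exactly the line-oriented
subset the writer produces — it is a purpose-built minimal RDF layer, not a
general parser — and `canonicalNTriples()` gives an order-insensitive form
for graph comparison. `queryAssociation()` reassembles a full record from
the graph; round-tripping is exercised per record in the tests.

## The synthetic corpus

`syntheticConfig()` / `generateReports()` emulate a mid-sized spontaneous
reporting corpus for validation: by default 50,000 reports over two
reporting years; twelve vaccine types with skewed usage weights (0.02–0.24)
and 1–3 vaccines per report (70/22/8%), reflecting frequent
co-administration; fifty symptom terms with background per-report
probabilities log-spaced from 0.08 down to 0.004, mimicking the heavy-tailed
frequency of MedDRA terms; sex mix 54% F / 40% M / 6% unknown, the
female-skewed composition typical of passive surveillance; and a
right-skewed adult age distribution with 5% missing ages. Planted signals
multiply a symptom's background probability for reports carrying a given
vaccine, optionally restricted to one sex ("both" targets F and M but not
U), capped at probability 1 — the simplest generative model whose
ground-truth PRR behaviour is controllable. Symptoms are drawn independently
given the vaccines: the generator has no symptom–symptom correlation, no
temporal trend, no age-dependent risk and no duplicate reports, so passing
recovery tests demonstrates correctness of the statistical machinery, not
robustness to the confounding, stimulated-reporting waves and data-quality
artefacts of real surveillance data.

Under the null (all multipliers 1) every pair's true reporting ratio is 1
and its estimate is roughly median-unbiased, so about half of well-supported
pairs (≥ 100 co-reports) land above 1; the suite asserts this fraction in
[0.35, 0.65] at 50,000 reports. A planted female-only multiplier of 5 on a
well-supported pair is recovered (female PRR > 1 and above the male
estimate) in at least 19 of 20 seeds. The test problem sizes — 50,000-report
corpora for calibration and recovery, 300-node graphs for the
Floyd–Warshall cross-check, 1,000 random instances for the index/Pearson
equivalence — were chosen to keep sampling error well below the asserted
tolerances while the whole suite still runs in a couple of minutes.

## Numerical and degenerate-input conventions

* Rounding for tabular output is half-up to 2 decimals (`roundHalfUp()`);
  base R's round-half-even is not used for printed tables.
* Undefined PRRs and PCCs propagate as `NA` everywhere; they are excluded by
  significance filters, imputed (with a warning) only at the clustering
  step, and exported to RDF as explicit markers.
* Empty networks yield all-zero metrics with a warning flag rather than an
  error, so per-stratum tables can include strata with no signal.
* All stochastic entry points take explicit integer seeds and restore the
  RNG state afterwards; pipeline runs with identical config and seed produce
  byte-identical artifacts (verified by checksum in the tests).

## Limitations

Desk-scale synthetic corpora cannot reproduce the published corpus-scale
network figures of real VAERS data (tens of thousands of significant pairs),
which require the full public download; the pipeline's correctness is
instead established by closed-form fixtures, independent oracles and
planted-signal recovery. PRR > 1 without any support threshold is a
deliberately permissive filter; the KS distance is descriptive only; and
the clustering is sensitive to the imputation of undefined similarities when
strata are sparse.
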