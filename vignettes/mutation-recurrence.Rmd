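---
title: "Recurrence analysis of somatic mutation catalogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence analysis of somatic mutation catalogs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mutrecur)
```

## The problem

Tumor genomes accumulate somatic mutations, most of which are
"passengers" private to one patient, while a small subset of "drivers"
recurs across patients because it confers a selective growth advantage.
Given a donor-level catalog of simple somatic mutations across many
cancer types, `mutrecur` quantifies this recurrence structure: how many
mutations are shared between donors, how quickly the fraction of donors
covered decays as the analysis is restricted to ever more recurrent
mutations, how per-donor mutation burden varies across cancer types, and
how similar cancer types are in which genes their recurrent mutations
hit.

## Mutation identity and recurrence

A mutation is identified by `(chromosome, start, ref, alt)` on a single
assumed genome build; coordinates are 1-based inclusive, `"-"` denotes
the empty side of a pure insertion or deletion, and chromosome labels are
normalized (`chr7` and `7` are the same chromosome). There is no
liftover: catalogs mixing builds must be harmonized upstream. The
**recurrence** of a mutation is the number of *distinct donors* in which
it is observed — a donor contributing the same mutation through several
rows (one per annotated consequence in SSM exports, or via two merged
national projects) counts once. Collapsing per-consequence rows keeps the
most severe consequence by a fixed priority (nonsense > frameshift >
missense > inframe > synonymous > splice/UTR > intron/intergenic; see
`consequence_priority()`), which prevents recurrence double-counting.

A mutation is **recurrent** when its recurrence is at least 2. This
threshold is fixed for all reported summaries (it is the standard
definition); exploratory code can pass `recurrent_min` explicitly.

Summaries are computed both per cancer type and on the pooled
"PanCancer" catalog, because the two views answer different questions
(recurrence within a cohort vs across all of cancer). National projects
of the same tumor type are merged *before* any counting
(`merge_projects()`, dropping the `-US`/`-UK`-style suffix); the pipeline
exposes `merge_national_projects = FALSE` to disable this.

### Donor denominators

Percentages of donors use the *roster* size — the enrolled cohort — not
the number of donors with passing calls. A cohort in which many donors
carry zero exonic mutations (low-burden leukemias and myeloid disorders
are real examples) would otherwise report inflated donor coverage.
When a donor manifest is supplied it defines the roster; otherwise the
roster defaults to the donors observed in the file.

### Formatting

Published per-cancer tables print cells like `171,314 (1.7%)`.
`format_percent()` uses half-up rounding at a fixed number of decimals
(default 1) rather than banker's rounding, because fixed-point half-up
is what such tables use; `table1_report()` adds thousands separators.

## Coverage curves and the 95% estimate

For thresholds $k = 1, 2, \dots$ the complementary cumulative
distributions are

$$F_{\mathrm{mut}}(k) = \frac{|\{m : r(m) \ge k\}|}{|\{m\}|}, \qquad
  F_{\mathrm{don}}(k) = \frac{|\{d : \exists m \in d,\ r(m) \ge k\}|}{N_{\mathrm{roster}}}$$

both non-increasing in $k$ with $F_{\mathrm{mut}}(1) = 1$. Re-indexing
donor coverage by mutation fraction gives the decay curve
$y(x)$: the fraction of donors recovered using only the top recurrent
fraction $x$ of mutations.

The decay is modeled as a two-parameter power law $y = A x^{b}$, fitted
by ordinary least squares in $(\log x, \log y)$. This family is an
*interpretation*, chosen as the minimal monotone form able to express
both fast-saturating regimes (a tiny fraction of hotspot mutations
covering nearly every donor) and slow ones (most mutations needed to
reach most donors); nothing in the data dictates it, and the fitted
numbers should be read as descriptive of a catalog, not mechanistic.
Numerical rules:

- points with $x = 0$ or $y = 0$ are excluded from the log fit (their
  count is reported) but retained for interpolation;
- a fit is refused below `min_points = 4` usable points, and the
  pipeline only fits cancer types with at least `min_fit_donors = 50`
  enrolled donors — below that the curve has too few informative
  thresholds for even a two-parameter family;
- the mutation fraction covering a target donor fraction (default 0.95)
  uses *observed data first*: if the target is bracketed by observed
  donor fractions the estimate is a monotone linear interpolation in
  $x$ (after enforcing monotonicity by a running maximum, which absorbs
  numerical jitter); only otherwise is the fitted law inverted,
  $x = (y_{\mathrm{target}}/A)^{1/b}$, clamped to $(0, 1]$. The result
  is tagged `"interpolated"` or `"extrapolated"` so downstream readers
  know which path produced it.

## Burden summaries

`donor_burden()` counts calls per roster donor after consequence
filtering (the default include-list, `exonic_consequences()`, covers
missense, synonymous, nonsense, start/stop-loss, frameshift, inframe
indel and generic exon classes; it is configurable and recorded in the
run manifest). Zero-burden donors are included by default — low-burden
cohorts can only have a median of ~1 mutation/donor if they are — and a
flag (`include_zero_donors = FALSE`) reproduces conventions that plot
mutation-bearing donors only. Quartiles use the median-of-halves rule
(middle value excluded from both halves for odd $n$); boxplot quartile
conventions differ across software, so the package fixes and documents
one.

## Tumor-type similarity

From the PanCancer-recurrent mutation set, each cancer type $t$ gets a
gene-level vector $v_t$ whose component for gene $g$ is the number of
donors of type $t$ with at least one recurrent mutation in $g$ — donor
counts, not binary flags or fractions, so cohort size and per-gene donor
penetrance both shape the profile (a per-donor-fraction normalization is
available but off by default). Only genes harboring recurrent mutations
become columns; calls without a gene label are excluded and counted.
Similarity is the cosine
$s(t, u) = \langle v_t, v_u \rangle / (\lVert v_t\rVert\,\lVert v_u\rVert)$,
in $[0, 1]$ for these non-negative vectors, and clustering is
agglomerative on distance $1 - s$ with average linkage (the conventional
default when only "hierarchical clustering" is specified; the linkage is
a parameter and is recorded in output metadata). Labels are sorted
before clustering so ties break deterministically.

Dendrograms serialize to Newick under the **height-halving convention**:
each leaf sits at depth half the height of its first merge, so the tree
is ultrametric and the path length between two leaves equals the merge
height of their lowest common cluster. Two types merging at height 0.2
serialize as `(A:0.1,B:0.1);`. This is the same convention `ape` uses
for `hclust` trees, so round-trips through standard phylogenetic tooling
are exact.

## The synthetic catalog generator

Real pan-cancer catalogs are controlled-access and far beyond desk
scale, so the package ships a generative model that reproduces the
*summary structure* the analysis depends on — it makes no claim of
mechanistic realism (no sequence context, no mutational signatures, no
copy number, no subclonality):

1. each donor's mutation count is negative binomial with mean
   `burden_mean` and dispersion `burden_dispersion` (heavy-tailed;
   a Poisson cannot produce the hypermutator tail seen in real data);
2. each drawn mutation is, with probability `shared_fraction`, a
   hotspot sampled from a pool of `shared_pool_size` mutations with
   Zipf popularity weights $w_i \propto i^{-\mathrm{zipf}}$
   (few "mountains", many "hills"), otherwise a private mutation with a
   globally unique synthetic coordinate — so the recurrence-1 class is
   exact by construction;
3. hotspot gene and consequence are fixed pool-wide; cancer types given
   the same `pool` label share hotspots, which is how co-clustering
   groups (and the planted-cluster validation) are constructed.

Under this model the recurrence CCD has a closed form
(`expected_recurrence_ccd()`): hotspot $i$ is carried by a donor with
probability $p_i = 1 - G(1 - q_i)$, where $q_i$ is its per-draw
probability and $G$ the negative-binomial probability generating
function, so its recurrence is $\mathrm{Binomial}(D, p_i)$ and expected
CCD counts are sums of binomial tails. The generator is validated
against this expectation (20 replicates of a 500-donor cohort agree
within 3 Monte-Carlo standard errors at every threshold $k \le 10$), and
all counting statistics are validated against naive brute-force oracles
on ~200-donor, ~5,000-call catalogs over 50 seeds; these problem sizes
make the full suite run in well under a minute while leaving Monte-Carlo
error far smaller than the effects being tested. Note the model treats
hotspot inclusions as independent across donors and pools expected
counts in a ratio, which matches the generator up to within-donor
draw-count correlations — empirically negligible at these sizes.

Preset panels document the regimes the defaults emulate: `"low-burden"`
(130 donors, median ~1 exonic mutation/donor), `"high-burden"`
(320 donors, median ~400), `"pan-mini"` (six types, ~590 donors, two
planted co-clustering pairs), and `"pan-scale"` (650 donors, ~1M drawn
calls, for throughput and conservation audits). Generated catalogs are
deterministic given (configuration, seed); the drawn per-donor burdens
are attached as an attribute so conservation (calls ≤ draws, equality
when `shared_fraction = 0`) can be audited exactly.

## Degenerate inputs and edge rules

- Empty scopes yield empty tables with a warning, not errors.
- A single-donor catalog has a coverage curve of $(1, 1)$ at $k = 1$ and
  $(0, 0)$ beyond; a single cancer type cannot be clustered (error).
- Cancer types whose every gene-profile entry is zero are a clustering
  error naming the type, since cosine similarity is undefined for zero
  vectors.
- Records with unparseable coordinates, invalid chromosome labels, or
  identical ref/alt alleles fail fast with line numbers by default;
  `on_bad_record = "skip"` drops and logs them.
- `filter_cancer_types()` defaults to `min_mutations = 4` in the
  pipeline, excluding degenerate cohorts (e.g. a project contributing
  only 3 detected mutations) whose summaries would be noise.

## Limitations

- The power-law decay model is descriptive; coverage estimates far
  outside the observed range (the `"extrapolated"` tag) inherit its
  assumptions and should be quoted with the tag.
- Cross-catalog comparability is limited by upstream heterogeneity in
  sequencing protocol and variant calling; the package audits internal
  consistency (stage conservation, roster coverage) but cannot correct
  acquisition bias or cohort-size imbalance.
- Donors are the counting unit; multiple specimens per donor must be
  deduplicated upstream (the reader deduplicates exact
  (donor, mutation) repeats but cannot detect two specimen IDs for one
  patient).
- Passing the synthetic validation demonstrates correctness of the
  counting, fitting and clustering machinery — not that real catalogs
  follow the generator's distributions.
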