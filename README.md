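# mutrecur

Recurrence analysis of pan-cancer somatic mutation catalogs.

Large cancer sequencing consortia release donor-level catalogs of simple
somatic mutations (SNVs and small indels) spanning dozens of cancer types
and millions of mutations. Most of those mutations are *private* — seen in
a single patient — while a small recurrent subset (mutations observed in
two or more donors) is strongly enriched for functionally relevant,
driver-like events. `mutrecur` is a toolkit for quantifying that
structure, aimed at computational cancer-genomics analysts working with
ICGC-style simple somatic mutation (SSM) exports:

- **Catalog IO** — read ICGC-dialect SSM TSVs, collapse per-consequence
  duplicate rows (keeping the most severe consequence), normalize
  chromosome labels, attach donor manifests, pool national projects of
  the same tumor type (`BRCA-US` + `BRCA-UK` → `BRCA`), and filter by
  consequence class or cohort size.
- **Recurrence statistics** — per-mutation donor recurrence
  `k(m) = #{donors carrying m}`, per-type and pooled ("PanCancer")
  summary tables (`count (pct%)` cells), and complementary cumulative
  distributions (CCDs): for each threshold *k*, the fraction of somatic
  mutations with recurrence ≥ *k* and the fraction of donors carrying at
  least one of them.
- **Coverage fitting** — the donors-vs-mutations curve y(x) (fraction of
  donors recovered by the top recurrent fraction x of mutations) is
  fitted as a power law `y = A·x^b` in log–log space, and inverted to
  estimate the mutation fraction covering a target donor fraction
  (default 95%), preferring interpolation of observed points whenever the
  target is bracketed.
- **Burden summaries** — per-donor exonic mutation counts (roster donors
  without calls count 0) and per-type five-number summaries; real
  catalogs span ~2.5 orders of magnitude between low-burden
  (median ≈ 1 mutation/donor) and high-burden (median ≈ 400) types.
- **Tumor-type clustering** — gene-level profiles counting, per cancer
  type, the donors with ≥ 1 PanCancer-recurrent mutation in each gene;
  cosine similarity between profiles; average-linkage hierarchical
  clustering on distance `1 − similarity`; Newick export.
- **Synthetic catalogs** — a seeded generator (negative-binomial donor
  burden, Zipf-weighted hotspot pool vs collision-free private mutations)
  plus a closed-form occupancy expectation for the recurrence CCD used to
  validate it, and presets from low-burden to a ~1M-call pan-cancer
  panel.

## Worked example

```r
library(mutrecur)

ct <- generate_catalog(preset_panel("pan-mini"), seed = 1)
ct <- merge_projects(ct)
ct <- filter_consequences(ct)              # exonic classes
ct <- filter_cancer_types(ct, min_mutations = 4)
ct
#> <mut_catalog> 60,559 calls | 55,997 unique mutations | 590 donors (542 with calls) | 6 cancer types

tab <- recurrence_counts(ct, "PanCancer")
recurrence_summary(tab, ct$roster)
#>        scope donors total_unique_mutations recurrent_mutations recurrent_pct
#> 1: PanCancer    590                  55997                 657          1.2%
#>    donors_with_recurrent donors_with_recurrent_pct
#> 1:                   464                     78.6%
```

Of 55,997 unique simulated mutations only 1.2% recur in ≥ 2 donors, yet
78.6% of the 590 donors carry at least one recurrent mutation — the
hallmark asymmetry of real pan-cancer catalogs.

```r
pts <- donors_vs_mutations(coverage_curve(tab, ct$roster))
fit <- fit_coverage_model(pts, scope = "PanCancer")
fit
#> <coverage_fit> scope PanCancer: donor_fraction = 1.191 * mutation_fraction^0.06937 (n = 54, log-log RSS = 0.764)
est <- mutation_fraction_at_coverage(pts, fit, 0.95)
#> 3.85% of mutations cover 95% of donors (extrapolated)

burden_summary(donor_burden(ct))
#>    cancer_type n_donors   min    q1 median    q3   max
#> 1:        LOWB      130     0   0.0    1.0   2.0     8
#> ...
#> 6:       HIGHB      100    23 221.5  327.0 514.5  1147
```

Burden medians span 1 → 327 mutations/donor (~2.5 orders of magnitude).
`run_pipeline(run_config(out_dir, sim = "pan-mini", seed = 1))` runs all
of the above plus cosine-similarity clustering in one call and writes
`table1.tsv`, `curves.tsv`, `fits.tsv`, `burden_summary.tsv`,
`similarity.tsv`, `dendrogram.nwk` and a reproducible `manifest.json`;
`inst/scripts/mutrecur-run.R` is a command-line wrapper over the same
entry point, and works identically on real SSM exports via `--ssm` /
`--manifest`.

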