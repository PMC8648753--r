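# stringaggr

Aggregation and visualization of STRING functional-enrichment results
across many differential-expression comparisons.

## The problem

Functional enrichment analysis asks whether a list of differentially
expressed (DE) genes over-represents annotation terms — KEGG pathways, GO
Biological Process / Molecular Function / Cellular Component categories,
Reactome pathways — relative to a background, and the STRING web service
answers that question for any submitted identifier list. For a single
contrast that is a few clicks; for a realistic design (three genotypes ×
two diets × two time points gives twelve pairwise contrasts) manually
retrieving, filtering and cross-referencing sixty enrichment tables is
error-prone drudgery. `stringaggr` automates the loop for bench scientists
and bioinformaticians alike: it takes one gene/fold-change table per
comparison, queries the STRING enrichment API (or an offline fixture
store) per comparison and direction of regulation, and condenses
everything into two aggregate table types per knowledge base, plus
clustermaps and bubble plots of the aggregates.

## The aggregation

For each knowledge base *k* and each term *t* significantly enriched
(FDR < α, default α = 0.05, strict) in at least one comparison:

- **summary table** — one row per *t* with
  `min_fdr = min_c FDR_k(t, c)` over the comparisons *c* containing *t*;
  `occurrence = #{c : t enriched in c}`;
  `all_genes = ∪_c genes_k(t, c)` and `common_genes = ∩_c genes_k(t, c)`,
  both ranging over the comparisons where *t* is enriched. An empty
  intersection is reported as the literal `No common gene`; a term seen in
  a single comparison as `n/a: just one condition`.
- **results table** — one row per *t* with one FDR column per comparison
  in the analysis; a comparison where *t* is not significantly enriched
  contributes exactly 1.

When up- and downregulated genes are analyzed separately (the default
mode), a term enriched in both lists of one comparison is merged by
keeping the **lowest** FDR and the union of matched gene labels.

Clustermaps plot the results matrix, optionally as −log10(FDR) with a
cutoff: cutoff 5 keeps exactly the terms whose best FDR is below 10⁻⁵.
Bubble plots show, per summary row, |all_genes| on x, |common_genes| as
marker size and the best FDR as color.

## Worked example (fully offline)

The fixture generator plants a known term/gene structure, so the run
below needs no network and its output is exactly reproducible:

```r
library(stringaggr)

spec <- fixture_spec(n_comparisons = 4, n_terms_per_kind = 5,
                     kinds = "KEGG", seed = 42)
de <- generate_de_tables(spec, "demo/de")               # 4 input tables
fx <- generate_enrichment_fixture(spec, "demo/enrichment")

report <- run_analysis(
  run_config(de, "demo/out", offline_fixture_dir = fx$dir))
#> analysis started: 4 input file(s), mode UP_DOWN_SEPARATE, species 10090, alpha 0.05
#> parsed comparison_01.tsv: 46 genes (0 rows skipped)
#>   comparison_01 [UP]: 2 significant term(s)
#>   comparison_01 [DOWN]: 1 significant term(s)
#> ...
#> aggregated KEGG: 5 term(s) -> results_KEGG.tsv, summary_KEGG.tsv
#> analysis finished: 4 comparison(s) aggregated, 0 failure(s)

report$aggregates$KEGG$summary[, c("term_id", "description", "min_fdr",
                                   "occurrence", "common_status")]
#>   term_id            description     min_fdr occurrence common_status
#> 1 map0005 synthetic KEGG term 05 1.88663e-08          4         genes
#> 2 map0002 synthetic KEGG term 02 8.87066e-08          3     no_common
#> 3 map0004 synthetic KEGG term 04 1.39032e-06          2         genes
#> 4 map0003 synthetic KEGG term 03 1.74908e-08          1        single
#> 5 map0001 synthetic KEGG term 01 4.33837e-03          1        single
```

Term `map0005` was significantly enriched in all 4 comparisons (best
FDR 1.9 × 10⁻⁸) and three genes are shared by all of them; `map0002`
recurs without any shared gene (its TSV cell reads `No common gene`);
`map0001`/`map0003` were each seen once (`n/a: just one condition`).
`demo/out/` now holds one subfolder of `UP_`/`DOWN_` STRING-format files
per comparison plus `results_KEGG.tsv` and `summary_KEGG.tsv`. Plots:

```r
m <- cluster_matrix(results_to_matrix(report$aggregates$KEGG$results,
                                      transform = TRUE))
render_clustermap(m, "demo/kegg_clustermap.png")
render_bubble_plot(summary_to_bubbles(report$aggregates$KEGG$summary),
                   "demo/kegg_bubbles.png")
```

A live analysis is the same call without `offline_fixture_dir`
(`run_config(de_files, "out", settings = analysis_settings(species = 10090))`),
which queries the STRING API with polite request spacing and retries.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stringaggr", package = "stringaggr"))')
$CLI run -o out --offline demo/enrichment demo/de/*.tsv
$CLI clustermap -o map.png --transform --cutoff 5 out/results_KEGG.tsv
$CLI bubble -o bubbles.png out/summary_KEGG.tsv
$CLI make-fixtures -o fixtures --comparisons 12 --seed 1
```

Exit codes: 0 success, 1 partial failure (some comparisons failed but the
run completed), 2 usage error.

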