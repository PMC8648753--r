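---
title: "Aggregating STRING functional enrichment across comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating STRING functional enrichment across comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stringaggr` automates a workflow that is conceptually simple but
operationally tedious: run STRING functional enrichment once per
differential-expression comparison (and per direction of regulation),
then cross-tabulate the enriched terms over all comparisons. This
vignette explains the procedure, its assumptions, the tunable parameters,
and the design choices made where reasonable alternatives existed.

## The procedure

Each input file is one comparison: a delimited table whose first column
is a gene identifier and whose second is a fold change; the file name is
the comparison label. Genes are split by direction and, per applicable
direction, sent to the STRING enrichment endpoint (or read from an
offline fixture store in the same format as STRING downloads). Records
from five knowledge bases are retained — KEGG, GO Process, GO Function,
GO Component and Reactome (`RCTM`) — and filtered at the significance
threshold. Directions are merged per comparison, then all comparisons
are aggregated per knowledge base into:

* a **summary** table: per term, the minimum FDR across comparisons, the
  occurrence count, and the union (`all_genes`) and intersection
  (`common_genes`) of the matched gene labels over the comparisons where
  the term is enriched;
* a **results** table: per term, one FDR per comparison, with the value 1
  standing in wherever the term was not significantly enriched. The
  constant 1 is a convention, not a probability statement: it makes the
  matrix dense, and `-log10(1) = 0` places absent terms at the neutral
  end of every color scale.

Two sentinels keep the summary honest: an empty intersection across two
or more comparisons is reported as `No common gene`, and a term seen in a
single comparison as `n/a: just one condition` (an "intersection" over
one set would misleadingly equal that set; the genes are still available
under `all_genes`).

The statistics themselves — hypergeometric enrichment tests and
multiple-testing correction — are STRING's job, performed server-side
against the selected species' genome or a user-supplied background list.
The package deliberately never recomputes them; it treats the returned
adjusted values (FDR) as the significance currency throughout. Where
interfaces or file formats speak of a "P-value score", the quantity used
is always that adjusted FDR; enrichment downloads expose only the FDR,
so aggregating on it keeps live and offline runs identical.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `species` | 10090 | NCBI taxon submitted to STRING (*Mus musculus*); any positive integer accepted |
| `api_version` | `"latest"` | main STRING host; a pinned tag such as `"11.0"` routes to the matching `version-x-y` host for reproducibility across STRING releases |
| `alpha` | 0.05 | significance threshold, applied strictly (`fdr < alpha`), dimensionless |
| `mode` | `UP_DOWN_SEPARATE` | also `UP_ONLY`, `DOWN_ONLY`, `ALL_TOGETHER`; controls which gene lists are submitted |
| `fc_convention` | `log-ratio` | sign split at 0; `linear-ratio` splits at 1 and rejects non-positive values |
| `background` | none | identifier list replacing the whole-genome background |

Defaults mirror the workflow the package automates: mouse data, the
current STRING release, 5% FDR, and separate retrieval for up- and
downregulated genes. With separate retrieval, a term enriched in both
directions of one comparison is merged by keeping the lowest FDR; gene
labels are unioned in that merge so the downstream union/intersection
columns account for every contributing gene — the merge rule itself only
fixes the FDR, and the union is the one completion that loses no genes.

Fold-change convention is configurable because input tables in the wild
carry either signed log-ratios or linear ratios; the log-ratio sign split
is the default since DE pipelines overwhelmingly report log2 fold
changes, and a sign split is well-defined for the negative values they
contain. Values exactly at the boundary (0, or 1 under linear ratios)
are neither up nor down but stay in the `ALL` list. Delimiters (tab,
comma, semicolon) are sniffed from the first line; one header row is
tolerated and detected by a non-numeric second field.

## Visualization semantics

`results_to_matrix()` applies, in order: term exclusion, the optional
`-log10` transform (FDR 1 maps to exactly 0), and the optional cutoff.
The cutoff is defined on transformed values and keeps a term iff its
*best* (maximum) transformed cell reaches the cutoff — equivalently its
minimum FDR is below `10^-cutoff`, so cutoff 5 means "best FDR below
0.00001". "Best" rather than mean was chosen because the plot's purpose
is to restrict to the most significant terms anywhere, and a mean over
mostly-absent (value 0) cells would punish rare but strong terms.
Requesting a cutoff without the transform is a usage error rather than a
silent reinterpretation, and filtering away every term raises an error
advising a lower cutoff instead of rendering an empty image.

Clustering uses average-linkage hierarchical clustering on Euclidean
distances, computed on the matrix exactly as passed (transformed if the
transform was applied) and on both axes by default — the standard
clustermap recipe. Clustering only permutes rows and columns; cell
values are never altered. Degenerate axes (a single row or column) fall
back to input order with a warning.

Bubble plots encode, per summary row, `|all_genes|` on x, `|common_genes|`
as marker area (0, drawn as an open circle, for sentinel rows) and the
minimum FDR as color, `-log10`-scaled by default. Terms are ordered by
descending x unless an explicit selection orders them; labels wrap at 40
characters. All image output (PNG at 300 dpi, SVG, PDF) is deterministic
— fixed fonts, no timestamps — so repeated renders are byte-identical and
figure regressions are testable by comparison.

## The fixture generator

`generate_enrichment_fixture()` is constructive, not statistical: it
plants, per term, the set of comparisons containing it, a common gene set
guaranteed present in each of them, per-comparison decoy genes drawn
without replacement across that term's comparisons (so the
cross-comparison intersection is *exactly* the planted set), a direction
per occurrence, and FDR values strictly below `alpha` spanning about
`1e-8` to `4e-2` (so cutoff filters split the terms non-trivially). Every
expected aggregate — minimum FDR, occurrence, union, intersection,
sentinel — is computed during generation, which makes all fixture-based
tests exact rather than tolerance-based. Boundary cases are always
planted: term 1 of each kind occurs once (single-condition sentinel),
term 2 recurs with no common gene, and term 3 is enriched in both
directions of one comparison (merge rule). FDRs are rounded to 6
significant digits at generation so files, ground truth and re-read
records are bit-identical.

What the fixtures do **not** emulate: real annotation structure (gene
labels are synthetic `GENE0001`-style symbols), correlated terms,
identifier-mapping noise, STRING server behaviour (rate limits, partial
responses), or any statistical relationship between the DE tables and
the enrichment results. Passing tests therefore demonstrate that the
bookkeeping — parsing, merging, set algebra, defaults, serialization,
plotting — is exact, not that STRING's enrichment itself is reproduced;
by design the package never recomputes enrichment.

## Numerical and degenerate-input choices

* Significance is strict (`fdr < alpha`); a term at exactly `alpha` is
  excluded.
* FDR serialization uses the shortest decimal representation that parses
  back to the identical double, so TSV round trips are exact.
* Row ordering in aggregate tables is descending occurrence, then
  ascending minimum FDR, then term id — recurrent, strong terms first,
  with a deterministic total order for reproducible files.
* A term id carrying different descriptions across comparisons keeps the
  first-seen description and warns.
* Duplicate gene ids within a DE table keep the first occurrence and
  warn; duplicate comparison labels are an error (they would silently
  collapse columns).
* A direction whose gene list is empty yields an empty record set, not
  an error; a comparison that fails entirely is reported and skipped so
  one bad file cannot abort an analysis, and a run where everything
  fails is an error carrying per-file diagnostics.

## Problem sizes

The test suite and the acceptance script run entirely offline on planted
fixtures of 3–12 comparisons and 4–10 terms per knowledge base — the
scale of the motivating twelve-contrast design — with property checks on
matrices up to 30 × 4. The whole suite completes in well under a minute;
the brute-force oracle used for cross-checking (naive per-term set
algebra over re-read raw files) is quadratic and comfortable at these
sizes.

## Known limitations

* Only the enrichment endpoint is wrapped; protein–protein interaction
  networks and the identifier-mapping endpoint are out of scope.
* Aggregation keys on term ids as returned by STRING; terms renamed or
  re-accessioned between STRING versions will not be unified (pin
  `api_version` for longitudinal projects).
* The live transport is a thin HTTP client (1 s spacing, 3 retries with
  exponential backoff); it is not exercised by the test suite, which
  substitutes the fixture transport through the same interface.
* `common_genes` intersects over the comparisons where a term is
  significant, not over all comparisons in the run — the documented
  meaning of "shared between all comparisons where the term is
  statistically significant" — so adding an unrelated comparison never
  empties the column.
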