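# Independent brute-force oracle for the aggregation: reads the raw
# STRING-format fixture files with base read.delim/strsplit (never through
# the package's readers) and recomputes every summary/results field with
# naive set algebra.

`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) <= 1L) return(list())
  lapply(strsplit(lines[-1L], "\t", fixed = TRUE), function(f) {
    list(term = f[[1L]], description = f[[2L]],
         fdr = as.numeric(f[[5L]]),
         genes = strsplit(f[[6L]], ",", fixed = TRUE)[[1L]])
  })
}

# per comparison: merge directions by keeping the lowest FDR and the gene
# union, term by term, with plain loops
oracle_comparison <- function(cmp_dir, kind, directions = c("UP", "DOWN")) {
  terms <- list()
  for (d in directions) {
    f <- file.path(cmp_dir, paste0(d, "_", kind, ".tsv"))
    if (!file.exists(f)) next
    for (rec in oracle_read_records(f)) {
      prev <- terms[[rec$term]]
      if (is.null(prev)) {
        terms[[rec$term]] <- rec
      } else {
        terms[[rec$term]]$fdr <- min(prev$fdr, rec$fdr)
        terms[[rec$term]]$genes <- union(prev$genes, rec$genes)
      }
    }
  }
  terms
}

# across comparisons: min FDR, occurrence, union and intersection of genes
oracle_aggregate <- function(fixture_dir, labels, kind,
                             directions = c("UP", "DOWN")) {
  per_cmp <- lapply(labels, function(lab) {
    oracle_comparison(file.path(fixture_dir, lab), kind, directions)
  })
  names(per_cmp) <- labels
  term_ids <- unique(unlist(lapply(per_cmp, names), use.names = FALSE))
  out <- list()
  for (t in term_ids) {
    fdrs <- numeric(0)
    gene_sets <- list()
    fdr_by_cmp <- stats::setNames(rep(1, length(labels)), labels)
    description <- NULL
    for (lab in labels) {
      rec <- per_cmp[[lab]][[t]]
      if (is.null(rec)) next
      fdrs <- c(fdrs, rec$fdr)
      gene_sets[[length(gene_sets) + 1L]] <- rec$genes
      fdr_by_cmp[[lab]] <- rec$fdr
      if (is.null(description)) description <- rec$description
    }
    common <- gene_sets[[1L]]
    for (g in gene_sets) common <- common[common %in% g]
    out[[t]] <- list(
      term_id = t, description = description,
      min_fdr = min(fdrs), occurrence = length(gene_sets),
      fdr_by_comparison = fdr_by_cmp,
      all_genes = sort(unique(unlist(gene_sets, use.names = FALSE))),
      common_genes = sort(unique(common))
    )
  }
  out
}

# tiny constructive comparison_enrichment builder for hand-made cases
make_comparison <- function(label, kind, terms, direction = "ALL") {
  recs <- enrichment_records(
    kind = kind,
    term_id = vapply(terms, `[[`, character(1), "term_id"),
    description = vapply(terms, function(t) {
      if (is.null(t$description)) t$term_id else t$description
    }, character(1)),
    fdr = vapply(terms, `[[`, numeric(1), "fdr"),
    genes = lapply(terms, `[[`, "genes")
  )
  comparison_enrichment(label, direction, recs)
}

local_fixture <- function(n_comparisons = 4L, n_terms = 6L, seed = 7L,
                          kinds = STRING_KINDS, env = parent.frame()) {
  td <- withr::local_tempdir(.local_envir = env)
  spec <- fixture_spec(n_comparisons = n_comparisons,
                       n_terms_per_kind = n_terms, kinds = kinds, seed = seed)
  fx <- generate_enrichment_fixture(spec, file.path(td, "enrichment"))
  de <- generate_de_tables(spec, file.path(td, "de"))
  list(root = td, spec = spec, fx = fx, de = de,
       out = file.path(td, "out"))
}
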