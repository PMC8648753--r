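# Aggregation of per-comparison enrichment records into the two
# per-knowledge-base table types: "summary" (one row per term with the best
# FDR, occurrence count and gene union/intersection) and "results" (one FDR
# column per comparison, 1 where absent).

#' Sentinel texts used in common_genes cells
#'
#' `"No common gene"` marks a term found in several comparisons whose
#' matched gene sets share nothing; `"n/a: just one condition"` marks a term
#' enriched in a single comparison, where an intersection across comparisons
#' is undefined (its genes are in `all_genes`).
#'
#' @format Named character vector with entries `no_common` and `single`.
#' @export
COMMON_GENE_SENTINELS <- c(no_common = "No common gene",
                           single = "n/a: just one condition")

#' Merge UP and DOWN enrichment records of one comparison
#'
#' When up- and downregulated genes are analyzed separately, a term can be
#' enriched in both lists. The merged record keeps the lowest FDR of the two
#' and the union of their matched gene labels, so downstream gene
#' union/intersection columns see every contributing gene. Terms present in
#' only one list pass through unchanged; ordering follows the UP list with
#' DOWN-only terms appended.
#'
#' @param up,down `enrichment_records` tables sharing one kind, term ids
#'   unique within each.
#' @return Merged `enrichment_records`.
#' @export
merge_directions <- function(up, down) {
  kinds <- unique(c(up$kind, down$kind))
  if (length(kinds) > 1L) {
    stop("cannot merge records of different kinds: ",
         paste(kinds, collapse = " vs "), call. = FALSE)
  }
  if (anyDuplicated(up$term_id) || anyDuplicated(down$term_id)) {
    stop("term ids must be unique within each direction", call. = FALSE)
  }
  if (nrow(down) == 0L) return(up)
  if (nrow(up) == 0L) return(down)

  merged <- up
  shared <- intersect(up$term_id, down$term_id)
  for (t in shared) {
    i <- match(t, merged$term_id)
    j <- match(t, down$term_id)
    if (down$fdr[[j]] < merged$fdr[[i]]) {
      merged$fdr[[i]] <- down$fdr[[j]]
      merged$p_value[[i]] <- down$p_value[[j]]
    }
    merged$genes[[i]] <- union(merged$genes[[i]], down$genes[[j]])
    merged$number_of_genes[[i]] <- length(merged$genes[[i]])
    merged$number_of_genes_in_background[[i]] <-
      max(merged$number_of_genes_in_background[[i]],
          down$number_of_genes_in_background[[j]],
          merged$number_of_genes[[i]])
  }
  down_only <- down[!down$term_id %in% up$term_id, , drop = FALSE]
  out <- rbind(merged, down_only)
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Merge directions within each comparison of an analysis
#'
#' Collapses the per-direction results of [fetch_enrichment()] to one
#' `comparison_enrichment` per comparison label, applying
#' [merge_directions()] kind by kind. Comparisons with a single direction
#' are relabeled but otherwise unchanged.
#'
#' @param per_direction List of `comparison_enrichment` objects (any mix of
#'   labels and directions).
#' @return List of merged `comparison_enrichment` objects, direction
#'   `"MERGED"`, one per distinct label, in first-appearance order.
#' @export
merge_comparison_directions <- function(per_direction) {
  labels <- unique(vapply(per_direction, `[[`, character(1), "label"))
  lapply(labels, function(lab) {
    parts <- Filter(function(ce) identical(ce$label, lab), per_direction)
    kinds <- unique(unlist(lapply(parts, function(ce) names(ce$records))))
    records <- list()
    for (k in intersect(STRING_KINDS, kinds)) {
      tabs <- lapply(parts, function(ce) {
        if (is.null(ce$records[[k]])) enrichment_records() else ce$records[[k]]
      })
      merged <- Reduce(merge_directions, tabs)
      if (nrow(merged) > 0L) records[[k]] <- merged
    }
    structure(list(label = lab, direction = "MERGED", records = records),
              class = "comparison_enrichment")
  })
}

collect_kind <- function(comparisons, kind) {
  labels <- vapply(comparisons, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate comparison labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  tabs <- lapply(comparisons, function(ce) {
    r <- ce$records[[kind]]
    if (is.null(r)) enrichment_records() else r
  })
  names(tabs) <- labels
  tabs
}

# per-term aggregation shared by build_summary / build_results
aggregate_terms <- function(tabs) {
  term_ids <- unique(unlist(lapply(tabs, `[[`, "term_id")))
  rows <- lapply(term_ids, function(t) {
    hits <- Filter(function(tab) t %in% tab$term_id, tabs)
    recs <- lapply(hits, function(tab) tab[match(t, tab$term_id), , drop = FALSE])
    descriptions <- vapply(recs, `[[`, character(1), "description")
    if (length(unique(descriptions)) > 1L) {
      warning("term ", t, " carries differing descriptions; keeping '",
              descriptions[[1L]], "'", call. = FALSE)
    }
    gene_sets <- lapply(recs, function(r) r$genes[[1L]])
    list(
      term_id = t,
      description = descriptions[[1L]],
      min_fdr = min(vapply(recs, `[[`, numeric(1), "fdr")),
      occurrence = length(hits),
      fdr_by_comparison = vapply(recs, `[[`, numeric(1), "fdr"),
      all_genes = sort(unique(unlist(gene_sets, use.names = FALSE))),
      common_genes = sort(Reduce(intersect, gene_sets))
    )
  })
  # descending occurrence, then ascending best FDR, then term id
  ord <- order(-vapply(rows, `[[`, integer(1), "occurrence"),
               vapply(rows, `[[`, numeric(1), "min_fdr"),
               vapply(rows, `[[`, character(1), "term_id"))
  rows[ord]
}

common_status <- function(row) {
  if (row$occurrence == 1L) "single"
  else if (length(row$common_genes) == 0L) "no_common"
  else "genes"
}

#' Build the summary-type table for one knowledge base
#'
#' One row per term enriched in at least one comparison, carrying the lowest
#' FDR ever observed across comparisons, the number of comparisons where the
#' term was significantly enriched (`occurrence`), the union of matched gene
#' labels over those comparisons (`all_genes`), and their intersection
#' (`common_genes`). The intersection ranges over the comparisons where the
#' term is present; when it is empty the row carries the
#' `"No common gene"` sentinel, and a term seen in a single comparison
#' carries `"n/a: just one condition"`.
#'
#' @param comparisons List of direction-merged `comparison_enrichment`
#'   objects with distinct labels, records already filtered at `alpha`.
#' @param kind One of [STRING_KINDS].
#' @return Data frame of class `summary_table` with columns `term_id`,
#'   `description`, `min_fdr`, `occurrence`, list columns `all_genes` and
#'   `common_genes`, and `common_status` (`"genes"`, `"no_common"` or
#'   `"single"`). Ordered by descending occurrence, then ascending
#'   `min_fdr`, then term id.
#' @export
build_summary <- function(comparisons, kind) {
  tabs <- collect_kind(comparisons, kind)
  rows <- aggregate_terms(tabs)
  statuses <- vapply(rows, common_status, character(1))
  df <- data.frame(
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    description = vapply(rows, `[[`, character(1), "description"),
    min_fdr = vapply(rows, `[[`, numeric(1), "min_fdr"),
    occurrence = vapply(rows, `[[`, integer(1), "occurrence"),
    stringsAsFactors = FALSE
  )
  df$all_genes <- lapply(rows, `[[`, "all_genes")
  df$common_genes <- lapply(seq_along(rows), function(i) {
    if (statuses[[i]] == "genes") rows[[i]]$common_genes else character(0)
  })
  df$common_status <- statuses
  attr(df, "kind") <- kind
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Build the results-type table for one knowledge base
#'
#' One row per term with its common genes (as in [build_summary()]) and one
#' FDR column per comparison in the analysis, in input order. Where a
#' comparison did not enrich significantly for the term, the cell holds
#' exactly 1 by convention, so the matrix is dense and directly plottable as
#' a clustermap.
#'
#' @inheritParams build_summary
#' @return Data frame of class `results_table`: columns `term_id`,
#'   `description`, list column `common_genes`, `common_status`, then one
#'   numeric column per comparison label. Row order matches
#'   [build_summary()].
#' @export
build_results <- function(comparisons, kind) {
  tabs <- collect_kind(comparisons, kind)
  labels <- names(tabs)
  rows <- aggregate_terms(tabs)
  statuses <- vapply(rows, common_status, character(1))
  df <- data.frame(
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    description = vapply(rows, `[[`, character(1), "description"),
    stringsAsFactors = FALSE
  )
  df$common_genes <- lapply(seq_along(rows), function(i) {
    if (statuses[[i]] == "genes") rows[[i]]$common_genes else character(0)
  })
  df$common_status <- statuses
  for (lab in labels) {
    df[[lab]] <- vapply(rows, function(row) {
      v <- row$fdr_by_comparison[names(row$fdr_by_comparison) == lab]
      if (length(v) == 1L) v else 1
    }, numeric(1))
  }
  attr(df, "kind") <- kind
  attr(df, "comparisons") <- labels
  class(df) <- c("results_table", "data.frame")
  df
}

#' Aggregate an analysis into per-kind summary and results tables
#'
#' Merges directions within each comparison, then builds both table types
#' for every knowledge base with at least one enriched term.
#'
#' @param per_direction List of `comparison_enrichment` objects as returned
#'   by [fetch_enrichment()] over all comparisons.
#' @return Named list over kinds; each element a list with `kind`,
#'   `summary` ([build_summary()]) and `results` ([build_results()]),
#'   of class `aggregate_tables`.
#' @export
aggregate_enrichment <- function(per_direction) {
  comparisons <- merge_comparison_directions(per_direction)
  kinds <- intersect(
    STRING_KINDS,
    unique(unlist(lapply(comparisons, function(ce) names(ce$records))))
  )
  out <- lapply(kinds, function(k) {
    structure(list(kind = k,
                   summary = build_summary(comparisons, k),
                   results = build_results(comparisons, k)),
              class = "aggregate_tables")
  })
  names(out) <- kinds
  out
}

#' @export
print.aggregate_tables <- function(x, ...) {
  cat("Aggregated", x$kind, "enrichment:", nrow(x$summary), "terms across",
      length(attr(x$results, "comparisons")), "comparisons\n")
  invisible(x)
}

serialize_common <- function(common_genes, common_status) {
  vapply(seq_along(common_status), function(i) {
    switch(common_status[[i]],
           genes = paste(sort(common_genes[[i]]), collapse = ","),
           no_common = COMMON_GENE_SENTINELS[["no_common"]],
           single = COMMON_GENE_SENTINELS[["single"]])
  }, character(1))
}

deserialize_common <- function(cells) {
  status <- ifelse(cells == COMMON_GENE_SENTINELS[["no_common"]], "no_common",
                   ifelse(cells == COMMON_GENE_SENTINELS[["single"]], "single",
                          "genes"))
  genes <- lapply(seq_along(cells), function(i) {
    if (status[[i]] != "genes") character(0)
    else strsplit(cells[[i]], ",", fixed = TRUE)[[1L]]
  })
  list(status = status, genes = genes)
}

# shortest round-tripping decimal representation (R >= 4.3 as.character)
format_fdr <- function(x) as.character(x)

#' Write a summary-type table to TSV
#'
#' Tab-separated, header row first; gene sets serialized as comma-joined
#' sorted labels and sentinels as their literal texts (see
#' [COMMON_GENE_SENTINELS]). [read_summary()] reproduces the rows.
#'
#' @param summary A `summary_table`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "summary_table"))
  lines <- paste(c("term_id", "description", "min_fdr", "occurrence",
                   "all_genes", "common_genes"), collapse = "\t")
  if (nrow(summary) > 0L) {
    lines <- c(lines, paste(
      summary$term_id, summary$description,
      format_fdr(summary$min_fdr), summary$occurrence,
      vapply(summary$all_genes, function(g) paste(sort(g), collapse = ","),
             character(1)),
      serialize_common(summary$common_genes, summary$common_status),
      sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a summary-type table written by [write_summary()]
#'
#' @param path File to read.
#' @param kind Knowledge base tag to attach; default inferred from a
#'   `summary_<kind>.tsv` filename when possible.
#' @return A `summary_table`.
#' @export
read_summary <- function(path, kind = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (is.null(kind)) {
    guess <- sub("^summary_", "", strip_extension(basename(path)))
    kind <- if (guess %in% STRING_KINDS) guess else NA_character_
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  common <- deserialize_common(vapply(rows, `[[`, character(1), 6L))
  df <- data.frame(
    term_id = vapply(rows, `[[`, character(1), 1L),
    description = vapply(rows, `[[`, character(1), 2L),
    min_fdr = vapply(rows, function(r) as.numeric(r[[3L]]), numeric(1)),
    occurrence = vapply(rows, function(r) as.integer(r[[4L]]), integer(1)),
    stringsAsFactors = FALSE
  )
  df$all_genes <- lapply(rows, function(r) {
    g <- strsplit(r[[5L]], ",", fixed = TRUE)[[1L]]
    g[nzchar(g)]
  })
  df$common_genes <- common$genes
  df$common_status <- common$status
  attr(df, "kind") <- kind
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Write a results-type table to TSV
#'
#' Tab-separated with one FDR column per comparison after the common-genes
#' column; sentinel serialization as in [write_summary()].
#'
#' @param results A `results_table`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "results_table"))
  labels <- attr(results, "comparisons")
  lines <- paste(c("term_id", "description", "common_genes", labels),
                 collapse = "\t")
  if (nrow(results) > 0L) {
    fdr_cols <- do.call(cbind, lapply(labels, function(lab) {
      format_fdr(results[[lab]])
    }))
    lines <- c(lines, paste(
      results$term_id, results$description,
      serialize_common(results$common_genes, results$common_status),
      apply(fdr_cols, 1L, paste, collapse = "\t"),
      sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a results-type table written by [write_results()]
#'
#' @param path File to read.
#' @param kind Knowledge base tag; default inferred from a
#'   `results_<kind>.tsv` filename when possible.
#' @return A `results_table`.
#' @export
read_results <- function(path, kind = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (is.null(kind)) {
    guess <- sub("^results_", "", strip_extension(basename(path)))
    kind <- if (guess %in% STRING_KINDS) guess else NA_character_
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  labels <- header[-(1:3)]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  common <- deserialize_common(vapply(rows, `[[`, character(1), 3L))
  df <- data.frame(
    term_id = vapply(rows, `[[`, character(1), 1L),
    description = vapply(rows, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  df$common_genes <- common$genes
  df$common_status <- common$status
  for (j in seq_along(labels)) {
    df[[labels[[j]]]] <- vapply(rows, function(r) as.numeric(r[[3L + j]]),
                                numeric(1))
  }
  attr(df, "kind") <- kind
  attr(df, "comparisons") <- labels
  class(df) <- c("results_table", "data.frame")
  df
}
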