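# Constructive offline fixtures: synthetic DE tables plus STRING-format
# enrichment files with planted term/gene overlap structure, generated
# together with their exact ground truth so every aggregation output can be
# checked without a network or any statistical tolerance.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic fixture
#'
#' Describes the planted structure of an offline test fixture: how many
#' comparisons, how many terms per knowledge base, the per-term gene-set
#' sizes and how many genes are planted as common to every comparison
#' containing a term. All randomness is driven by `seed`; the same spec
#' always yields byte-identical files and the same ground truth.
#'
#' The generated plan always covers the boundary cases of the aggregation:
#' the first term of each kind occurs in exactly one comparison
#' (single-condition sentinel), the second occurs in several comparisons
#' with no planted common gene and disjoint decoys (no-common-gene
#' sentinel), and the third is enriched in both the UP and DOWN gene lists
#' of one comparison (exercising the lowest-FDR merge rule).
#'
#' @param n_comparisons Number of comparisons (the worked layout uses 12).
#' @param n_terms_per_kind Terms generated for each knowledge base.
#' @param genes_per_term Length-2 integer range of genes matched per term
#'   and comparison.
#' @param planted_common_size Length-2 integer range for the planted common
#'   gene set; must fit inside `genes_per_term`.
#' @param kinds Knowledge bases to generate (default all five).
#' @param alpha Significance ceiling; planted FDR values are strictly below
#'   it.
#' @param seed Integer seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_comparisons = 12L, n_terms_per_kind = 8L,
                         genes_per_term = c(4L, 8L),
                         planted_common_size = c(1L, max(1L, genes_per_term[[1L]] - 1L)),
                         kinds = STRING_KINDS, alpha = 0.05, seed = 1L) {
  stopifnot(n_comparisons >= 1L, n_terms_per_kind >= 1L,
            length(genes_per_term) == 2L,
            genes_per_term[[1L]] >= 1L,
            genes_per_term[[2L]] >= genes_per_term[[1L]],
            all(kinds %in% STRING_KINDS))
  if (planted_common_size[[2L]] > genes_per_term[[2L]]) {
    stop("infeasible fixture: planted common gene sets (up to ",
         planted_common_size[[2L]], ") cannot exceed genes_per_term maximum (",
         genes_per_term[[2L]], ")", call. = FALSE)
  }
  structure(
    list(n_comparisons = as.integer(n_comparisons),
         n_terms_per_kind = as.integer(n_terms_per_kind),
         genes_per_term = as.integer(genes_per_term),
         planted_common_size = as.integer(planted_common_size),
         kinds = kinds, alpha = alpha, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Fixture spec: ", x$n_comparisons, " comparisons, ",
      x$n_terms_per_kind, " terms x ", length(x$kinds),
      " kinds, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

fixture_labels <- function(spec) {
  sprintf("comparison_%02d", seq_len(spec$n_comparisons))
}

kind_term_prefix <- c(KEGG = "map", Process = "GO:BP", Function = "GO:MF",
                      Component = "GO:CC", RCTM = "R-SYN")

# planted FDR strictly below alpha, spanning ~1e-8 .. alpha/1.25 so cutoff
# filters split the terms non-trivially
draw_fdr <- function(n, alpha) {
  upper <- -log10(alpha / 1.25)
  signif(10^(-stats::runif(n, upper, 8)), 6L)
}

build_fixture_plan <- function(spec) {
  labels <- fixture_labels(spec)
  n <- spec$n_comparisons
  gene_pool <- sprintf("GENE%04d", seq_len(5000L))
  plan <- list()
  for (kind in spec$kinds) {
    terms <- list()
    for (i in seq_len(spec$n_terms_per_kind)) {
      term_id <- sprintf("%s%04d", kind_term_prefix[[kind]], i)
      occ <- if (i == 1L) 1L
      else if (i == 2L) min(3L, max(2L, n))
      else sample.int(n, 1L)
      occ <- min(occ, n)
      in_comparisons <- sort(sample.int(n, occ))
      planted <- if (i == 2L && n >= 2L) character(0) else {
        size <- sample(seq(spec$planted_common_size[[1L]],
                           spec$planted_common_size[[2L]]), 1L)
        sample(gene_pool, size)
      }
      # decoys drawn without replacement across this term's comparisons so
      # the cross-comparison intersection is exactly the planted set
      decoy_pool <- sample(setdiff(gene_pool, planted))
      used <- 0L
      per_cmp <- list()
      for (j in in_comparisons) {
        lo <- max(spec$genes_per_term[[1L]], length(planted) + 1L)
        hi <- max(lo, spec$genes_per_term[[2L]])
        n_genes <- sample(seq(lo, hi), 1L)
        n_decoys <- n_genes - length(planted)
        decoys <- decoy_pool[used + seq_len(n_decoys)]
        used <- used + n_decoys
        both <- (i == 3L && j == in_comparisons[[1L]])
        direction <- if (both) "BOTH" else sample(c("UP", "DOWN"), 1L)
        fdr <- draw_fdr(if (both) 2L else 1L, spec$alpha)
        per_cmp[[labels[[j]]]] <- list(
          genes = sample(c(planted, decoys)),
          direction = direction,
          fdr = fdr
        )
      }
      terms[[term_id]] <- list(
        term_id = term_id,
        description = sprintf("synthetic %s term %02d", kind, i),
        planted_common = planted,
        per_comparison = per_cmp
      )
    }
    plan[[kind]] <- terms
  }
  list(labels = labels, plan = plan)
}

plan_ground_truth <- function(plan, kind) {
  terms <- plan$plan[[kind]]
  rows <- lapply(terms, function(tm) {
    fdrs <- vapply(tm$per_comparison, function(p) min(p$fdr), numeric(1))
    gene_sets <- lapply(tm$per_comparison, `[[`, "genes")
    occurrence <- length(tm$per_comparison)
    common <- sort(Reduce(intersect, gene_sets))
    status <- if (occurrence == 1L) "single"
    else if (length(common) == 0L) "no_common"
    else "genes"
    list(term_id = tm$term_id, description = tm$description,
         min_fdr = min(fdrs), occurrence = occurrence,
         fdr_by_comparison = fdrs,
         all_genes = sort(unique(unlist(gene_sets, use.names = FALSE))),
         common_genes = if (status == "genes") common else character(0),
         common_status = status)
  })
  rows <- unname(rows)
  ord <- order(-vapply(rows, `[[`, integer(1), "occurrence"),
               vapply(rows, `[[`, numeric(1), "min_fdr"),
               vapply(rows, `[[`, character(1), "term_id"))
  rows <- rows[ord]
  df <- data.frame(
    term_id = vapply(rows, `[[`, character(1), "term_id"),
    description = vapply(rows, `[[`, character(1), "description"),
    min_fdr = vapply(rows, `[[`, numeric(1), "min_fdr"),
    occurrence = vapply(rows, `[[`, integer(1), "occurrence"),
    stringsAsFactors = FALSE
  )
  df$all_genes <- lapply(rows, `[[`, "all_genes")
  df$common_genes <- lapply(rows, `[[`, "common_genes")
  df$common_status <- vapply(rows, `[[`, character(1), "common_status")
  df$fdr_by_comparison <- lapply(rows, `[[`, "fdr_by_comparison")
  attr(df, "kind") <- kind
  class(df) <- c("summary_table", "data.frame")
  df
}

#' Generate synthetic differential-expression tables
#'
#' Writes one gene/fold-change TSV per comparison (header row, tab
#' delimiter, signed log-ratio fold changes) so complete runs can be
#' exercised offline in the exact input format users supply. Deterministic
#' for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
generate_de_tables <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- fixture_labels(spec)
  with_seed(spec$seed, {
    paths <- vapply(labels, function(lab) {
      n_genes <- sample(30:60, 1L)
      genes <- sample(sprintf("GENE%04d", seq_len(5000L)), n_genes)
      fc <- round(stats::rnorm(n_genes, sd = 2), 4L)
      fc[fc == 0] <- 0.1
      path <- file.path(dir, paste0(lab, ".tsv"))
      writeLines(c("gene\tlog2_fold_change",
                   paste(genes, format(fc, trim = TRUE), sep = "\t")),
                 path, useBytes = TRUE)
      path
    }, character(1))
    invisible(unname(paths))
  })
}

#' Generate a STRING-format enrichment fixture with ground truth
#'
#' Materializes the planted structure of a [fixture_spec()] as
#' per-comparison folders of `UP_`/`DOWN_`/`ALL_` `<kind>.tsv` files — the
#' layout [string_transport_fixture()] serves and a live run stores — plus
#' the exact expected aggregation. A term planned for both directions of a
#' comparison appears in the UP and DOWN files with two different FDR
#' values; its ground-truth FDR is their minimum. `ALL_` files carry the
#' direction-merged records, so the same fixture serves the
#' `ALL_TOGETHER` mode. Ground-truth tables are also written to
#' `ground_truth_<kind>.tsv` for inspection.
#'
#' @param spec A [fixture_spec()].
#' @param dir Fixture root directory (created if needed).
#' @return List with `dir`, `labels`, and `ground_truth` — a named list
#'   over kinds of `summary_table`-shaped data frames carrying an extra
#'   `fdr_by_comparison` list column with the per-comparison planted FDRs.
#' @export
generate_enrichment_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  built <- with_seed(spec$seed + 1L, build_fixture_plan(spec))
  labels <- built$labels

  for (lab in labels) {
    cmp_dir <- file.path(dir, lab)
    dir.create(cmp_dir, showWarnings = FALSE)
    for (kind in spec$kinds) {
      terms <- built$plan[[kind]]
      per_dir <- list(UP = list(), DOWN = list(), ALL = list())
      for (tm in terms) {
        p <- tm$per_comparison[[lab]]
        if (is.null(p)) next
        rec <- function(fdr, genes) {
          enrichment_records(kind = kind, term_id = tm$term_id,
                             description = tm$description, fdr = fdr,
                             genes = list(genes))
        }
        if (p$direction == "BOTH") {
          per_dir$UP[[length(per_dir$UP) + 1L]] <- rec(p$fdr[[1L]], p$genes)
          per_dir$DOWN[[length(per_dir$DOWN) + 1L]] <- rec(p$fdr[[2L]], p$genes)
        } else {
          per_dir[[p$direction]][[length(per_dir[[p$direction]]) + 1L]] <-
            rec(p$fdr[[1L]], p$genes)
        }
        per_dir$ALL[[length(per_dir$ALL) + 1L]] <- rec(min(p$fdr), p$genes)
      }
      for (d in names(per_dir)) {
        recs <- if (length(per_dir[[d]]) == 0L) enrichment_records()
        else do.call(rbind, per_dir[[d]])
        recs$kind <- rep_len(kind, nrow(recs))
        class(recs) <- c("enrichment_records", "data.frame")
        write_enrichment_tsv(recs, file.path(cmp_dir,
                                             paste0(d, "_", kind, ".tsv")))
      }
    }
  }

  ground_truth <- lapply(spec$kinds, function(kind) plan_ground_truth(built, kind))
  names(ground_truth) <- spec$kinds
  for (kind in spec$kinds) {
    gt <- ground_truth[[kind]]
    gt$fdr_by_comparison <- NULL
    class(gt) <- c("summary_table", "data.frame")
    write_summary(gt, file.path(dir, paste0("ground_truth_", kind, ".tsv")))
  }
  list(dir = dir, labels = labels, ground_truth = ground_truth)
}
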