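# small hand-built results/summary tables for visualization tests

toy_results <- function(fdr_matrix, labels = NULL) {
  n <- nrow(fdr_matrix)
  labs <- colnames(fdr_matrix)
  df <- data.frame(
    term_id = if (is.null(labels)) sprintf("T%02d", seq_len(n)) else labels,
    description = if (is.null(labels)) sprintf("term %02d", seq_len(n)) else labels,
    stringsAsFactors = FALSE
  )
  df$common_genes <- replicate(n, character(0), simplify = FALSE)
  df$common_status <- rep("no_common", n)
  for (j in seq_along(labs)) df[[labs[[j]]]] <- fdr_matrix[, j]
  attr(df, "comparisons") <- labs
  attr(df, "kind") <- "KEGG"
  class(df) <- c("results_table", "data.frame")
  df
}

toy_summary <- function(all_genes, common_genes, status, min_fdr) {
  n <- length(min_fdr)
  df <- data.frame(term_id = sprintf("T%02d", seq_len(n)),
                   description = sprintf("term %02d", seq_len(n)),
                   min_fdr = min_fdr, occurrence = rep(2L, n),
                   stringsAsFactors = FALSE)
  df$all_genes <- all_genes
  df$common_genes <- common_genes
  df$common_status <- status
  attr(df, "kind") <- "KEGG"
  class(df) <- c("summary_table", "data.frame")
  df
}
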