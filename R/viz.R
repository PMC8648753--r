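# Visualization of aggregated enrichment: results-type tables become
# term x comparison FDR clustermaps, summary-type tables become bubble
# plots (x = union gene count, size = shared gene count, color = best FDR).

term_labels_for <- function(results) {
  labs <- results$description
  labs[!nzchar(labs)] <- results$term_id[!nzchar(labs)]
  dup <- labs %in% labs[duplicated(labs)]
  labs[dup] <- paste0(labs[dup], " (", results$term_id[dup], ")")
  labs
}

#' Convert a results-type table to a plottable term matrix
#'
#' Builds the dense term x comparison FDR matrix underlying a clustermap,
#' with the customizations offered for it: exclusion of unwanted terms,
#' `-log10` transformation of the FDR values (an absent-term cell, FDR 1,
#' maps to exactly 0), and a significance cutoff. With cutoff `c` a term is
#' retained iff its best (maximum) transformed value is at least `c` —
#' equivalently its minimum FDR is below `10^-c`, so cutoff 5 keeps exactly
#' the terms with FDR < 0.00001 somewhere. The cutoff therefore requires the
#' transform.
#'
#' @param results A `results_table` (see [build_results()], [read_results()]).
#' @param transform Logical; apply `-log10` to every cell.
#' @param cutoff Optional non-negative real; drop terms whose maximum
#'   transformed value is below it.
#' @param exclude Character vector of term labels (descriptions or term ids)
#'   to drop before anything else.
#' @return Object of class `term_matrix`: list with `values` (numeric
#'   matrix, terms x comparisons, dimnames set), `transformed` flag, and
#'   optional `row_hclust`/`col_hclust` after [cluster_matrix()].
#' @export
results_to_matrix <- function(results, transform = FALSE, cutoff = NULL,
                              exclude = character()) {
  stopifnot(inherits(results, "results_table"))
  if (nrow(results) == 0L) {
    stop("results table has no terms to plot", call. = FALSE)
  }
  if (!is.null(cutoff) && !transform) {
    stop("a cutoff is defined on -log10(FDR) values; set transform = TRUE",
         call. = FALSE)
  }
  labels <- term_labels_for(results)
  keep <- !(labels %in% exclude | results$term_id %in% exclude |
              results$description %in% exclude)
  results <- results[keep, , drop = FALSE]
  labels <- labels[keep]

  comparisons <- attr(results, "comparisons")
  values <- as.matrix(as.data.frame(results)[, comparisons, drop = FALSE])
  dimnames(values) <- list(labels, comparisons)
  if (transform) {
    values <- -log10(values)
    values[results_matrix_is_one(values)] <- 0
  }
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
    retained <- apply(values, 1L, max) >= cutoff
    if (!any(retained)) {
      stop("no term reaches -log10(FDR) cutoff ", cutoff,
           "; try a lower cutoff", call. = FALSE)
    }
    values <- values[retained, , drop = FALSE]
  }
  if (nrow(values) == 0L) {
    stop("all terms excluded; nothing to plot", call. = FALSE)
  }
  structure(list(values = values, transformed = transform, cutoff = cutoff),
            class = "term_matrix")
}

# -log10(1) can come back as -0; normalize the sign so fdr = 1 -> exactly 0
results_matrix_is_one <- function(values) {
  values == 0
}

#' @export
print.term_matrix <- function(x, ...) {
  cat("Term matrix: ", nrow(x$values), " terms x ", ncol(x$values),
      " comparisons (", if (x$transformed) "-log10(FDR)" else "raw FDR",
      if (!is.null(x$cutoff)) paste0(", cutoff ", x$cutoff), ")\n", sep = "")
  invisible(x)
}

#' Hierarchically cluster a term matrix
#'
#' Reorders rows and/or columns by average-linkage hierarchical clustering
#' of Euclidean distances computed on the matrix as passed (transformed
#' values if the transform was applied). Cell values are only permuted,
#' never changed. An axis with fewer than two entries cannot be clustered
#' and falls back to the input order with a warning.
#'
#' @param matrix A `term_matrix`.
#' @param cluster_rows,cluster_cols Logical.
#' @return The `term_matrix` with reordered `values` and the `hclust`
#'   objects stored in `row_hclust`/`col_hclust` (used by
#'   [render_clustermap()] to draw dendrograms).
#' @export
cluster_matrix <- function(matrix, cluster_rows = TRUE, cluster_cols = TRUE) {
  stopifnot(inherits(matrix, "term_matrix"))
  v <- matrix$values
  if (cluster_rows) {
    if (nrow(v) < 2L) {
      warning("fewer than 2 rows; skipping row clustering", call. = FALSE)
    } else {
      hc <- stats::hclust(stats::dist(v, method = "euclidean"),
                          method = "average")
      v <- v[hc$order, , drop = FALSE]
      matrix$row_hclust <- hc
    }
  }
  if (cluster_cols) {
    if (ncol(v) < 2L) {
      warning("fewer than 2 columns; skipping column clustering", call. = FALSE)
    } else {
      hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                          method = "average")
      v <- v[, hc$order, drop = FALSE]
      matrix$col_hclust <- hc
    }
  }
  matrix$values <- v
  matrix
}

open_image_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 300),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported image format '.", ext, "'; use .png, .svg or .pdf",
              call. = FALSE))
}

#' Render a clustermap of a term matrix
#'
#' Draws the heatmap with dendrograms for any axis clustered by
#' [cluster_matrix()]. Transformed matrices use a sequential palette
#' anchored at 0 (white = FDR 1, dark = strong significance); raw-FDR
#' matrices invert the palette so smaller FDR is more intense. Rendering is
#' deterministic for a fixed matrix and style, so repeated renders are
#' byte-identical.
#'
#' @param matrix A `term_matrix`.
#' @param path Output image (`.png` at 300 dpi, `.svg`, or `.pdf`).
#' @param width,height Figure size in inches.
#' @param palette Colors interpolated for the fill scale.
#' @return `path`, invisibly.
#' @export
render_clustermap <- function(matrix, path, width = 8, height = 6,
                              palette = c("#f7f7f7", "#fdae61", "#a50026")) {
  stopifnot(inherits(matrix, "term_matrix"))
  v <- matrix$values
  if (length(v) == 0L) stop("empty matrix", call. = FALSE)
  colors <- grDevices::colorRampPalette(palette)(100)
  if (matrix$transformed) {
    breaks <- seq(0, max(v, 1e-9), length.out = 101L)
  } else {
    colors <- rev(colors)
    breaks <- seq(0, 1, length.out = 101L)
  }
  # pheatmap applies the leaf order itself, so hand it the matrix in the
  # original hclust label order; the drawn order equals cluster_matrix's
  if (!is.null(matrix$row_hclust)) {
    v <- v[match(matrix$row_hclust$labels, rownames(v)), , drop = FALSE]
  }
  if (!is.null(matrix$col_hclust)) {
    v <- v[, match(matrix$col_hclust$labels, colnames(v)), drop = FALSE]
  }
  open_image_device(path, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(
    v,
    cluster_rows = if (is.null(matrix$row_hclust)) FALSE else matrix$row_hclust,
    cluster_cols = if (is.null(matrix$col_hclust)) FALSE else matrix$col_hclust,
    color = colors, breaks = breaks,
    main = if (matrix$transformed) "-log10(FDR)" else "FDR",
    fontsize = 8
  )
  invisible(path)
}

wrap_label <- function(x, width = 40L) {
  vapply(x, function(s) paste(strwrap(s, width = width), collapse = "\n"),
         character(1), USE.NAMES = FALSE)
}

#' Convert a summary-type table to bubble-plot data
#'
#' One datum per term: `x` is the number of genes annotated to the term
#' across all comparisons (`|all_genes|`), `size` the number of genes shared
#' by every comparison where the term is enriched (`|common_genes|`, 0 for
#' sentinel rows), and `color_value` the term's best (minimum) FDR.
#'
#' @param summary A `summary_table`.
#' @param selection Optional character vector of term labels (descriptions
#'   or term ids) restricting and ordering the plot; unknown labels are an
#'   error.
#' @return Data frame with columns `term_label`, `x`, `size`, `color_value`,
#'   ordered by `selection` or by descending `x`.
#' @export
summary_to_bubbles <- function(summary, selection = NULL) {
  stopifnot(inherits(summary, "summary_table"))
  if (nrow(summary) == 0L) stop("summary table has no terms", call. = FALSE)
  labels <- summary$description
  labels[!nzchar(labels)] <- summary$term_id[!nzchar(labels)]
  df <- data.frame(
    term_label = labels,
    x = vapply(summary$all_genes, length, integer(1)),
    size = ifelse(summary$common_status == "genes",
                  vapply(summary$common_genes, length, integer(1)), 0L),
    color_value = summary$min_fdr,
    stringsAsFactors = FALSE
  )
  if (!is.null(selection)) {
    idx <- match(selection, df$term_label)
    idx[is.na(idx)] <- match(selection[is.na(idx)], summary$term_id)
    if (anyNA(idx)) {
      stop("unknown terms in selection: ",
           paste(selection[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    df <- df[idx, , drop = FALSE]
  } else {
    df <- df[order(-df$x, df$term_label), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Render a bubble plot of summary data
#'
#' Terms on the y axis, union gene count on x, marker area proportional to
#' the shared gene count, and color encoding the best FDR (on a `-log10`
#' scale when `log_color = TRUE`). Terms with no shared genes are drawn as
#' open circles. Labels wrap at 40 characters. Deterministic for fixed data
#' and style.
#'
#' @param data Data frame from [summary_to_bubbles()].
#' @param path Output image (`.png`, `.svg`, `.pdf`).
#' @param width,height Figure size in inches.
#' @param log_color Color by `-log10(min FDR)` rather than raw FDR.
#' @param palette Colors interpolated for the color scale.
#' @return `path`, invisibly.
#' @export
render_bubble_plot <- function(data, path, width = 7, height = 6,
                               log_color = TRUE,
                               palette = c("#2c7bb6", "#ffffbf", "#d7191c")) {
  stopifnot(is.data.frame(data), nrow(data) > 0L,
            all(c("term_label", "x", "size", "color_value") %in% names(data)))
  cv <- if (log_color) -log10(data$color_value) else data$color_value
  ramp <- grDevices::colorRampPalette(palette)(100)
  span <- range(cv)
  idx <- if (diff(span) == 0) rep(50L, length(cv)) else
    1L + as.integer(99 * (cv - span[[1L]]) / diff(span))
  cols <- ramp[idx]

  open_image_device(path, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  n <- nrow(data)
  y <- rev(seq_len(n))
  graphics::par(mar = c(4.5, 16, 3, 2))
  graphics::plot(data$x, y, type = "n", yaxt = "n", ylab = "",
                 xlab = "genes annotated to term (all comparisons)",
                 ylim = c(0.5, n + 0.5),
                 xlim = range(data$x) + c(-1, 1) * max(1, 0.08 * diff(range(data$x))),
                 main = if (log_color) "best FDR (-log10 color scale)"
                 else "best FDR")
  max_size <- max(data$size, 1L)
  cex <- 0.8 + 3.2 * sqrt(data$size / max_size)
  filled <- data$size > 0L
  graphics::points(data$x[filled], y[filled], pch = 21, cex = cex[filled],
                   bg = cols[filled], col = "grey30")
  if (any(!filled)) {
    graphics::points(data$x[!filled], y[!filled], pch = 1, cex = 1,
                     col = "grey30")
  }
  graphics::axis(2, at = y, labels = wrap_label(data$term_label), las = 2,
                 cex.axis = 0.7)
  invisible(path)
}
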