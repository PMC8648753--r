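#' Parse a differential-expression table
#'
#' Reads a delimited text file containing one gene identifier and one fold
#' change per row. The file name (without directory or extension) becomes the
#' comparison label, so `treatment_A_vs_B.tsv` labels the comparison
#' `treatment_A_vs_B`. Only the first two columns are used: column 1 is the
#' gene identifier, column 2 the fold change; extra columns are ignored.
#'
#' A single header row is tolerated: if the second field of the first row is
#' not interpretable as a number, that row is skipped. Data rows whose fold
#' change cannot be parsed (e.g. `NA`, empty) are skipped and counted in the
#' `n_skipped` field. Duplicated gene identifiers keep the first occurrence
#' and raise a warning.
#'
#' @param path Path to a `.tsv`/`.csv`/`.txt` file, UTF-8 encoded.
#' @param delimiter Field separator. `NULL` (default) sniffs tab, comma or
#'   semicolon from the first line; otherwise a single character.
#' @return An object of class `de_table`: a list with components `label`
#'   (character scalar), `genes` (character vector), `fold_change` (numeric
#'   vector, same length), and `n_skipped` (integer count of dropped rows).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tFC", "Apoe\t2.1", "Ldlr\t-1.3"), f)
#' de <- parse_de_table(f)
#' de$genes
#' @export
parse_de_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty differential-expression file: ", path, call. = FALSE)
  }
  sep <- if (is.null(delimiter)) sniff_delimiter(lines[[1L]]) else delimiter

  fields <- strsplit(lines, sep, fixed = TRUE)
  bad_shape <- vapply(fields, length, integer(1)) < 2L
  if (all(bad_shape)) {
    stop("no row in ", path, " has at least two '", sep, "'-separated fields",
         call. = FALSE)
  }

  n_skipped <- 0L
  # header: first row whose second field is non-numeric
  if (!bad_shape[[1L]] && is.na(parse_number(fields[[1L]][[2L]]))) {
    fields <- fields[-1L]
    bad_shape <- bad_shape[-1L]
  }

  genes <- character(0)
  fc <- numeric(0)
  for (i in seq_along(fields)) {
    if (bad_shape[[i]]) {
      n_skipped <- n_skipped + 1L
      next
    }
    g <- trimws(fields[[i]][[1L]])
    v <- parse_number(fields[[i]][[2L]])
    if (!nzchar(g) || is.na(v) || !is.finite(v)) {
      n_skipped <- n_skipped + 1L
      next
    }
    genes <- c(genes, g)
    fc <- c(fc, v)
  }
  if (length(genes) == 0L) {
    stop("no parseable gene/fold-change rows in ", path, call. = FALSE)
  }

  dup <- duplicated(genes)
  if (any(dup)) {
    warning("duplicate gene identifiers in ", basename(path), " (",
            paste(unique(genes[dup]), collapse = ", "),
            "); keeping first occurrence", call. = FALSE)
    genes <- genes[!dup]
    fc <- fc[!dup]
  }

  structure(
    list(
      label = strip_extension(basename(path)),
      genes = genes,
      fold_change = fc,
      n_skipped = n_skipped
    ),
    class = "de_table"
  )
}

#' @export
print.de_table <- function(x, ...) {
  cat("DE table '", x$label, "': ", length(x$genes), " genes (",
      sum(x$fold_change > 0), " up, ", sum(x$fold_change < 0), " down; ",
      x$n_skipped, " rows skipped)\n", sep = "")
  invisible(x)
}

sniff_delimiter <- function(line) {
  counts <- vapply(c("\t", ",", ";"),
                   function(s) lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L)) "\t" else names(counts)[[which.max(counts)]]
}

parse_number <- function(x) {
  suppressWarnings(as.numeric(trimws(x)))
}

strip_extension <- function(x) {
  sub("\\.[^.]*$", "", x)
}

#' Split a DE table into up- and downregulated gene sets
#'
#' Partitions the genes of a [parse_de_table()] result according to the fold
#' change sign convention. Under `"log-ratio"` (default) positive values are
#' upregulated and negative values downregulated; zero is neither but is kept
#' in `all`. Under `"linear-ratio"` values above 1 are upregulated, values in
#' (0, 1) downregulated, exactly 1 neither; non-positive values are an error
#' because a linear expression ratio cannot be zero or negative.
#'
#' @param table A `de_table`.
#' @param convention `"log-ratio"` or `"linear-ratio"`.
#' @return An object of class `gene_sets`: list with character vectors `up`,
#'   `down` and `all` (input order preserved, `all` = every gene).
#' @export
split_directions <- function(table, convention = c("log-ratio", "linear-ratio")) {
  stopifnot(inherits(table, "de_table"))
  convention <- match.arg(convention)
  fc <- table$fold_change
  if (convention == "log-ratio") {
    up <- table$genes[fc > 0]
    down <- table$genes[fc < 0]
  } else {
    if (any(fc <= 0)) {
      stop("linear-ratio fold changes must be positive; offending genes: ",
           paste(utils::head(table$genes[fc <= 0], 5L), collapse = ", "),
           call. = FALSE)
    }
    up <- table$genes[fc > 1]
    down <- table$genes[fc < 1]
  }
  structure(
    list(up = up, down = down, all = table$genes),
    class = "gene_sets"
  )
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene sets: ", length(x$up), " up, ", length(x$down), " down, ",
      length(x$all), " total\n", sep = "")
  invisible(x)
}

#' Load a statistical background list
#'
#' Reads a headerless file with one identifier per line, for use as the
#' statistical background of the enrichment analysis (the default background
#' is the whole genome of the selected species). Blank lines are skipped,
#' identifiers are whitespace-trimmed, duplicates removed.
#'
#' @param path Path to the background file.
#' @return Character vector of unique identifiers.
#' @export
load_background <- function(path) {
  ids <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) {
    stop("background file ", path, " contains no identifiers", call. = FALSE)
  }
  ids
}
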