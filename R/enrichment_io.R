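# STRING-style enrichment tables: tab-delimited, one header row, one term
# per row, matching the files downloadable from the STRING website.

ENRICHMENT_HEADER <- c("#term ID", "term description", "observed gene count",
                       "background gene count", "false discovery rate",
                       "matching proteins in your network (labels)")

kind_from_filename <- function(path) {
  base <- strip_extension(basename(path))
  kind <- sub("^(UP|DOWN|ALL)_", "", base)
  if (!kind %in% STRING_KINDS) {
    stop("cannot infer knowledge base from filename '", basename(path),
         "'; expected <DIRECTION>_<kind>.tsv with kind in ",
         paste(STRING_KINDS, collapse = "/"), call. = FALSE)
  }
  kind
}

#' Read a STRING-format enrichment table
#'
#' Parses a tab-delimited enrichment file as downloaded from STRING (or
#' written by [write_enrichment_tsv()]): one header row, then one term per
#' row with term ID, description, observed and background gene counts, FDR,
#' and the comma-separated matched gene labels. The knowledge base is taken
#' from the filename (`<DIRECTION>_<kind>.tsv` or `<kind>.tsv`).
#'
#' @param path File to read.
#' @param kind Knowledge base; default inferred from the filename.
#' @return `enrichment_records` (possibly zero rows for a header-only file).
#' @export
read_enrichment_tsv <- function(path, kind = kind_from_filename(path)) {
  force(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    stop("malformed enrichment file ", path, ": empty (line 1)", call. = FALSE)
  }
  if (length(lines) == 1L) {
    return(enrichment_records())
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 6L) {
      stop("malformed enrichment file ", path, ": expected 6 fields at line ",
           i + 1L, call. = FALSE)
    }
    counts <- suppressWarnings(as.numeric(rows[[i]][3:5]))
    if (anyNA(counts)) {
      stop("malformed enrichment file ", path, ": non-numeric count/FDR at line ",
           i + 1L, call. = FALSE)
    }
  }
  enrichment_records(
    kind = kind,
    term_id = vapply(rows, `[[`, character(1), 1L),
    description = vapply(rows, `[[`, character(1), 2L),
    fdr = vapply(rows, function(r) as.numeric(r[[5L]]), numeric(1)),
    genes = lapply(rows, function(r) {
      g <- strsplit(r[[6L]], ",", fixed = TRUE)[[1L]]
      g[nzchar(g)]
    }),
    number_of_genes_in_background =
      vapply(rows, function(r) as.integer(r[[4L]]), integer(1))
  )
}

#' Write enrichment records as a STRING-format table
#'
#' Serializes one knowledge base's records to the tab-delimited layout of a
#' STRING download. FDR values use the shortest decimal representation that
#' parses back to the same double, so a read/write round trip reproduces
#' the records exactly.
#'
#' @param records `enrichment_records`, all of one kind.
#' @param path Destination file; conventionally `<DIRECTION>_<kind>.tsv`.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  kinds <- unique(records$kind)
  if (length(kinds) > 1L) {
    stop("write_enrichment_tsv expects records of a single kind, got: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  lines <- paste(ENRICHMENT_HEADER, collapse = "\t")
  if (nrow(records) > 0L) {
    lines <- c(lines, paste(
      records$term_id,
      records$description,
      records$number_of_genes,
      records$number_of_genes_in_background,
      as.character(records$fdr),
      vapply(records$genes, paste, character(1), collapse = ","),
      sep = "\t"
    ))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
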