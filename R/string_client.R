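#' The five knowledge bases aggregated by the package
#'
#' STRING reports enrichment against several annotation sources; this package
#' aggregates the five used throughout: KEGG Pathways (`"KEGG"`), GO
#' Biological Process (`"Process"`), GO Molecular Function (`"Function"`),
#' GO Cellular Component (`"Component"`) and Reactome Pathways (`"RCTM"`).
#'
#' @format Character vector of length 5.
#' @export
STRING_KINDS <- c("KEGG", "Process", "Function", "Component", "RCTM")

#' Analysis settings for enrichment retrieval
#'
#' Bundles the options controlling one analysis run. Defaults follow the
#' tool's conventions: *Mus musculus* (NCBI taxon 10090), the latest STRING
#' release, significance threshold 0.05 (strict: a term is retained when its
#' FDR is lower than `alpha`), and separate retrieval for up- and
#' downregulated genes.
#'
#' @param species Positive integer NCBI taxonomy identifier (10090 = mouse,
#'   9606 = human).
#' @param api_version `"latest"` for the main STRING host, or a pinned
#'   release tag such as `"11.0"` routed to the corresponding version host.
#' @param background Optional character vector of identifiers (see
#'   [load_background()]) restricting the statistical background; `NULL`
#'   uses the whole genome of `species`.
#' @param alpha Significance threshold in (0, 1) applied as `fdr < alpha`.
#' @param mode One of `"UP_DOWN_SEPARATE"` (default: enrichment retrieved
#'   for up- and downregulated genes separately, then merged),
#'   `"UP_ONLY"`, `"DOWN_ONLY"`, or `"ALL_TOGETHER"`.
#' @return Object of class `analysis_settings`.
#' @export
analysis_settings <- function(species = 10090,
                              api_version = "latest",
                              background = NULL,
                              alpha = 0.05,
                              mode = c("UP_DOWN_SEPARATE", "UP_ONLY",
                                       "DOWN_ONLY", "ALL_TOGETHER")) {
  mode <- match.arg(mode)
  if (!is.numeric(species) || length(species) != 1L || is.na(species) ||
      species < 1 || species != round(species)) {
    stop("species must be a positive integer NCBI taxonomy id", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(background)) {
    background <- unique(trimws(as.character(background)))
    background <- background[nzchar(background)]
  }
  structure(
    list(species = as.integer(species), api_version = as.character(api_version),
         background = background, alpha = alpha, mode = mode),
    class = "analysis_settings"
  )
}

#' @export
print.analysis_settings <- function(x, ...) {
  cat("Analysis settings: species", x$species, "| STRING", x$api_version,
      "| alpha", x$alpha, "| mode", x$mode,
      if (is.null(x$background)) "| genome background"
      else paste("| custom background of", length(x$background)), "\n")
  invisible(x)
}

string_host <- function(api_version) {
  if (identical(api_version, "latest")) {
    "https://string-db.org"
  } else {
    # e.g. "11.0" -> https://version-11-0.string-db.org
    sprintf("https://version-%s.string-db.org",
            gsub(".", "-", api_version, fixed = TRUE))
  }
}

#' Build an enrichment request descriptor
#'
#' Assembles the endpoint URL and parameter map for one STRING
#' functional-enrichment query. The descriptor is consumed by a transport
#' (see [string_transport_http()] and [string_transport_fixture()]); it is
#' exposed so request construction can be inspected without touching the
#' network.
#'
#' @param genes Non-empty character vector of identifiers.
#' @param settings An [analysis_settings()] object.
#' @return List with `url` (the JSON enrichment endpoint on the
#'   version-appropriate host) and `params` (named list: newline-joined
#'   `identifiers`, `species`, `caller_identity`, and
#'   `background_string_identifiers` when a background is set).
#' @export
build_enrichment_request <- function(genes, settings) {
  stopifnot(inherits(settings, "analysis_settings"))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    stop("cannot build an enrichment request from an empty gene list",
         call. = FALSE)
  }
  params <- list(
    identifiers = paste(genes, collapse = "\n"),
    species = settings$species,
    caller_identity = "stringaggr"
  )
  if (!is.null(settings$background)) {
    params$background_string_identifiers <-
      paste(settings$background, collapse = "\n")
  }
  list(
    url = paste0(string_host(settings$api_version), "/api/json/enrichment"),
    params = params
  )
}

#' Construct a table of enrichment records
#'
#' Internal-facing constructor for the canonical record container: a
#' data frame with one row per enriched term and a list column `genes`
#' holding the matched gene labels.
#'
#' @param kind Character vector (recycled) of knowledge-base kinds.
#' @param term_id,description Character vectors.
#' @param fdr Numeric vector of adjusted significance values in (0, 1].
#' @param genes List of character vectors (matched preferred names).
#' @param number_of_genes_in_background Integer vector; defaults to the
#'   observed gene counts when unknown.
#' @param p_value Optional numeric vector (downloaded tables carry only FDR).
#' @return Data frame of class `enrichment_records`.
#' @export
enrichment_records <- function(kind = character(), term_id = character(),
                               description = character(), fdr = numeric(),
                               genes = list(),
                               number_of_genes_in_background = NULL,
                               p_value = NULL) {
  n <- length(term_id)
  ngenes <- vapply(genes, length, integer(1))
  if (is.null(number_of_genes_in_background)) {
    number_of_genes_in_background <- ngenes
  }
  if (is.null(p_value)) p_value <- rep(NA_real_, n)
  df <- data.frame(
    kind = rep_len(as.character(kind), n),
    term_id = as.character(term_id),
    description = as.character(description),
    number_of_genes = ngenes,
    number_of_genes_in_background = as.integer(number_of_genes_in_background),
    fdr = as.numeric(fdr),
    p_value = as.numeric(p_value),
    stringsAsFactors = FALSE
  )
  df$genes <- unname(genes)
  class(df) <- c("enrichment_records", "data.frame")
  df
}

# category labels STRING uses for the five aggregated knowledge bases;
# other categories (Pfam, InterPro, SMART, ...) are dropped on parsing
normalize_kind <- function(category) {
  map <- c(KEGG = "KEGG", Process = "Process", Function = "Function",
           Component = "Component", RCTM = "RCTM",
           `KEGG Pathways` = "KEGG", `Reactome Pathways` = "RCTM")
  unname(map[category])
}

#' Parse a STRING enrichment payload into records
#'
#' Converts the decoded JSON response of the STRING enrichment endpoint — a
#' list of per-term field maps — into an [enrichment_records()] table.
#' Entries from the five supported knowledge bases are kept; entries from
#' other categories (e.g. Pfam, InterPro) are dropped and counted in the
#' `n_dropped` attribute of the result.
#'
#' @param payload List of named lists, each with at least `category`,
#'   `term`, `fdr` and `preferredNames` (matched gene labels, either a
#'   character vector or a comma-separated string).
#' @return `enrichment_records` with attribute `n_dropped`.
#' @export
parse_enrichment_payload <- function(payload) {
  if (length(payload) == 0L) {
    out <- enrichment_records()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  required <- c("category", "term", "fdr", "preferredNames")
  for (i in seq_along(payload)) {
    missing <- setdiff(required, names(payload[[i]]))
    if (length(missing) > 0L) {
      stop("malformed enrichment payload: entry ", i,
           " is missing field '", missing[[1L]], "'", call. = FALSE)
    }
  }
  kinds <- normalize_kind(vapply(payload, function(e) as.character(e$category),
                                 character(1)))
  keep <- !is.na(kinds)
  kept <- payload[keep]
  genes <- lapply(kept, function(e) {
    g <- e$preferredNames
    if (length(g) == 1L && grepl(",", g)) g <- strsplit(g, ",", fixed = TRUE)[[1L]]
    as.character(g)
  })
  out <- enrichment_records(
    kind = kinds[keep],
    term_id = vapply(kept, function(e) as.character(e$term), character(1)),
    description = vapply(kept, function(e) {
      if (is.null(e$description)) "" else as.character(e$description)
    }, character(1)),
    fdr = vapply(kept, function(e) as.numeric(e$fdr), numeric(1)),
    genes = genes,
    number_of_genes_in_background = vapply(kept, function(e) {
      if (is.null(e$number_of_genes_in_background)) NA_integer_
      else as.integer(e$number_of_genes_in_background)
    }, integer(1)),
    p_value = vapply(kept, function(e) {
      if (is.null(e$p_value)) NA_real_ else as.numeric(e$p_value)
    }, numeric(1))
  )
  bg <- out$number_of_genes_in_background
  out$number_of_genes_in_background <- ifelse(is.na(bg), out$number_of_genes, bg)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Keep only significantly enriched records
#'
#' Retains records whose FDR is strictly lower than `alpha`, preserving
#' order. The strict inequality means a term at exactly `alpha` is dropped.
#'
#' @param records `enrichment_records`.
#' @param alpha Threshold in (0, 1).
#' @return Filtered `enrichment_records`.
#' @export
filter_significant <- function(records, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  out <- records[records$fdr < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Live HTTP transport for the STRING enrichment API
#'
#' Returns a transport function posting requests to the STRING server, with
#' polite spacing between calls (>= 1 s), three retries with exponential
#' backoff, and an explicit caller identity. A transport maps a request
#' descriptor from [build_enrichment_request()] to a decoded JSON payload
#' (list of field maps) for [parse_enrichment_payload()].
#'
#' @param pause Minimum seconds between consecutive requests.
#' @param max_retries Attempts before giving up.
#' @return A function `(request) -> payload`.
#' @seealso [string_transport_fixture()] for the offline equivalent.
#' @export
string_transport_http <- function(pause = 1, max_retries = 3L) {
  last_call <- 0
  function(request) {
    wait <- pause - (as.numeric(Sys.time()) - last_call)
    if (wait > 0) Sys.sleep(wait)
    body <- paste(
      vapply(names(request$params), function(k) {
        paste0(k, "=", utils::URLencode(as.character(request$params[[k]]),
                                        reserved = TRUE))
      }, character(1)),
      collapse = "&"
    )
    for (attempt in seq_len(max_retries)) {
      payload <- tryCatch({
        con <- url(paste0(request$url, "?", body))
        on.exit(close(con), add = TRUE)
        jsonlite::fromJSON(paste(readLines(con, warn = FALSE), collapse = "\n"),
                           simplifyVector = FALSE)
      }, error = function(e) e)
      last_call <<- as.numeric(Sys.time())
      if (!inherits(payload, "error")) return(payload)
      if (attempt < max_retries) Sys.sleep(pause * 2^attempt)
    }
    stop("STRING request failed after ", max_retries, " attempts: ",
         conditionMessage(payload), call. = FALSE)
  }
}

#' Offline fixture transport
#'
#' Returns a transport that serves enrichment results from STRING-format
#' tab-delimited files on disk instead of the network, so complete analyses
#' run offline. The fixture directory holds one subdirectory per comparison
#' label, containing `<DIRECTION>_<kind>.tsv` files as written by
#' [write_enrichment_tsv()] or [generate_enrichment_fixture()] — the same
#' layout the live run stores for later inspection.
#'
#' @param dir Fixture root directory.
#' @return A function `(request) -> payload` keyed by the `label` and
#'   `direction` fields that [fetch_enrichment()] attaches to the request.
#' @export
string_transport_fixture <- function(dir) {
  if (!dir.exists(dir)) {
    stop("fixture directory not found: ", dir, call. = FALSE)
  }
  force(dir)
  function(request) {
    cmp_dir <- file.path(dir, request$label)
    if (!dir.exists(cmp_dir)) {
      stop("no fixture folder for comparison '", request$label, "'",
           call. = FALSE)
    }
    files <- list.files(cmp_dir,
                        pattern = paste0("^", request$direction, "_.*\\.tsv$"),
                        full.names = TRUE)
    payload <- list()
    for (f in files) {
      recs <- read_enrichment_tsv(f)
      for (i in seq_len(nrow(recs))) {
        payload[[length(payload) + 1L]] <- list(
          category = recs$kind[[i]],
          term = recs$term_id[[i]],
          description = recs$description[[i]],
          number_of_genes = recs$number_of_genes[[i]],
          number_of_genes_in_background = recs$number_of_genes_in_background[[i]],
          fdr = recs$fdr[[i]],
          preferredNames = recs$genes[[i]]
        )
      }
    }
    payload
  }
}

directions_for_mode <- function(mode) {
  switch(mode,
         UP_DOWN_SEPARATE = c("UP", "DOWN"),
         UP_ONLY = "UP",
         DOWN_ONLY = "DOWN",
         ALL_TOGETHER = "ALL")
}

gene_list_for_direction <- function(genesets, direction) {
  switch(direction, UP = genesets$up, DOWN = genesets$down, ALL = genesets$all)
}

#' Retrieve enrichment for one comparison
#'
#' Issues one enrichment request per direction applicable under the analysis
#' mode (`UP` and `DOWN` for `UP_DOWN_SEPARATE`, a single direction for the
#' other modes), parses the payloads and filters at `settings$alpha`. A
#' direction with an empty gene list yields an empty record set rather than
#' an error, mirroring comparisons whose lists are too small to enrich.
#'
#' @param genesets A `gene_sets` object from [split_directions()].
#' @param settings [analysis_settings()].
#' @param transport Transport function (see [string_transport_http()],
#'   [string_transport_fixture()]).
#' @param label Comparison label, attached to results and fixture lookups.
#' @return List of `comparison_enrichment` objects, one per direction, each
#'   a list with `label`, `direction`, and `records` — a named list of
#'   `enrichment_records` keyed by kind (kinds without hits are absent).
#' @export
fetch_enrichment <- function(genesets, settings, transport, label) {
  stopifnot(inherits(genesets, "gene_sets"),
            inherits(settings, "analysis_settings"))
  dirs <- directions_for_mode(settings$mode)
  lapply(dirs, function(d) {
    genes <- gene_list_for_direction(genesets, d)
    recs <- if (length(genes) == 0L) {
      enrichment_records()
    } else {
      request <- build_enrichment_request(genes, settings)
      request$label <- label
      request$direction <- d
      filter_significant(parse_enrichment_payload(transport(request)),
                         settings$alpha)
    }
    comparison_enrichment(label, d, recs)
  })
}

#' Assemble a per-comparison, per-direction enrichment result
#'
#' @param label Comparison label.
#' @param direction `"UP"`, `"DOWN"` or `"ALL"`.
#' @param records A single `enrichment_records` table (split by kind
#'   internally) or an already-keyed list of per-kind tables.
#' @return Object of class `comparison_enrichment`.
#' @export
comparison_enrichment <- function(label, direction, records) {
  if (inherits(records, "data.frame")) {
    records <- split_records_by_kind(records)
  }
  structure(list(label = label, direction = direction, records = records),
            class = "comparison_enrichment")
}

split_records_by_kind <- function(records) {
  out <- list()
  for (k in intersect(STRING_KINDS, unique(records$kind))) {
    sub <- records[records$kind == k, , drop = FALSE]
    if (anyDuplicated(sub$term_id)) {
      stop("duplicate term ids within kind ", k, call. = FALSE)
    }
    rownames(sub) <- NULL
    out[[k]] <- sub
  }
  out
}

#' @export
print.comparison_enrichment <- function(x, ...) {
  counts <- vapply(x$records, nrow, integer(1))
  cat("Enrichment for '", x$label, "' [", x$direction, "]: ",
      if (length(counts) == 0L) "no terms"
      else paste(paste0(names(counts), "=", counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
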