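payload_entry <- function(category, term, fdr, genes, ...) {
  c(list(category = category, term = term, fdr = fdr,
         preferredNames = genes, description = paste("desc", term)),
    list(...))
}

test_that("settings default to mouse, latest version, alpha 0.05, UP/DOWN separate", {
  s <- analysis_settings()
  expect_identical(s$species, 10090L)
  expect_identical(s$api_version, "latest")
  expect_identical(s$alpha, 0.05)
  expect_identical(s$mode, "UP_DOWN_SEPARATE")
  expect_null(s$background)
})

test_that("settings validate species, alpha and mode", {
  expect_error(analysis_settings(species = 0), "positive integer")
  expect_error(analysis_settings(alpha = 1), "between 0 and 1")
  expect_error(analysis_settings(mode = "BOGUS"))
  expect_identical(analysis_settings(species = 9606)$species, 9606L)
})

test_that("request descriptors target the version-appropriate host", {
  s <- analysis_settings(species = 10090)
  req <- build_enrichment_request(c("G1", "G2"), s)
  expect_match(req$url, "^https://string-db\\.org/api/json/enrichment$")
  expect_identical(req$params$identifiers, "G1\nG2")
  expect_identical(req$params$species, 10090L)
  expect_true(nzchar(req$params$caller_identity))

  pinned <- build_enrichment_request(c("G1"), analysis_settings(api_version = "11.0"))
  expect_match(pinned$url, "version-11-0\\.string-db\\.org")
})

test_that("a background is forwarded and an empty gene list refused", {
  s <- analysis_settings(background = c("B1", "B2"))
  req <- build_enrichment_request("G1", s)
  expect_identical(req$params$background_string_identifiers, "B1\nB2")
  expect_error(build_enrichment_request(character(0), s), "empty gene list")
})

test_that("payload parsing maps the five categories and drops the rest", {
  payload <- list(
    payload_entry("KEGG", "mmu04640", 0.001, c("Cd19", "Cd22")),
    payload_entry("Process", "GO:0002376", 0.01, c("Cd19")),
    payload_entry("Pfam", "PF00001", 0.001, c("X1")),
    payload_entry("InterPro", "IPR000001", 0.002, c("X2")),
    payload_entry("RCTM", "R-MMU-1", 0.03, c("A", "B", "C"))
  )
  recs <- parse_enrichment_payload(payload)
  expect_identical(nrow(recs), 3L)
  expect_identical(attr(recs, "n_dropped"), 2L)
  expect_identical(recs$kind, c("KEGG", "Process", "RCTM"))
  expect_identical(recs$number_of_genes, c(2L, 1L, 3L))
  expect_identical(recs$genes[[1]], c("Cd19", "Cd22"))
  # kind partition: kept + dropped = payload length
  expect_identical(nrow(recs) + attr(recs, "n_dropped"), length(payload))
})

test_that("empty and malformed payloads are handled", {
  expect_identical(nrow(parse_enrichment_payload(list())), 0L)
  bad <- list(list(category = "KEGG", term = "t1", preferredNames = "G1"))
  expect_error(parse_enrichment_payload(bad), "missing field 'fdr'")
})

test_that("significance filtering is strict (fdr < alpha)", {
  recs <- enrichment_records(kind = "KEGG", term_id = c("t1", "t2", "t3"),
                             description = c("a", "b", "c"),
                             fdr = c(0.01, 0.05, 0.049),
                             genes = list("G1", "G2", "G3"))
  kept <- filter_significant(recs, 0.05)
  expect_identical(kept$term_id, c("t1", "t3"))
  expect_identical(nrow(filter_significant(recs, 1 - 1e-9)), 3L)
})

test_that("filtering equals an elementwise oracle on random FDRs", {
  withr::local_seed(11)
  fdr <- round(stats::runif(50), 4)
  fdr[fdr == 0] <- 0.5
  recs <- enrichment_records(kind = "Process", term_id = sprintf("t%02d", 1:50),
                             description = sprintf("d%02d", 1:50), fdr = fdr,
                             genes = replicate(50, "G1", simplify = FALSE))
  for (alpha in c(0.05, 0.2, 0.9)) {
    kept <- filter_significant(recs, alpha)
    expect_identical(kept$term_id, recs$term_id[fdr < alpha])
  }
})

test_that("fetch issues one request per applicable direction", {
  seen <- character(0)
  transport <- function(request) {
    seen <<- c(seen, request$direction)
    list(payload_entry("KEGG", "t1", 0.001, c("G1")))
  }
  sets <- structure(list(up = "G1", down = "G2", all = c("G1", "G2")),
                    class = "gene_sets")
  out <- fetch_enrichment(sets, analysis_settings(), transport, "cmpA")
  expect_identical(seen, c("UP", "DOWN"))
  expect_identical(vapply(out, `[[`, character(1), "direction"), c("UP", "DOWN"))
  expect_identical(out[[1]]$label, "cmpA")

  seen <- character(0)
  fetch_enrichment(sets, analysis_settings(mode = "ALL_TOGETHER"), transport, "c")
  expect_identical(seen, "ALL")
  seen <- character(0)
  fetch_enrichment(sets, analysis_settings(mode = "DOWN_ONLY"), transport, "c")
  expect_identical(seen, "DOWN")
})

test_that("an empty direction yields an empty record map, not an error", {
  transport <- function(request) list(payload_entry("KEGG", "t1", 0.001, "G2"))
  sets <- structure(list(up = character(0), down = "G2", all = "G2"),
                    class = "gene_sets")
  out <- fetch_enrichment(sets, analysis_settings(), transport, "cmp")
  up <- out[[which(vapply(out, `[[`, character(1), "direction") == "UP")]]
  expect_length(up$records, 0)
})

test_that("canned payloads pass through the transport unchanged", {
  payload <- list(payload_entry("KEGG", "mmu04142", 0.004, c("Ctsd", "Lamp1")),
                  payload_entry("Component", "GO:0005764", 0.02, c("Lamp1")))
  transport <- function(request) payload
  sets <- structure(list(up = "Ctsd", down = character(0), all = "Ctsd"),
                    class = "gene_sets")
  out <- fetch_enrichment(sets, analysis_settings(mode = "UP_ONLY"),
                          transport, "cmp")
  direct <- filter_significant(parse_enrichment_payload(payload), 0.05)
  expect_identical(out[[1]]$records$KEGG$term_id, direct$term_id[direct$kind == "KEGG"])
  expect_identical(out[[1]]$records$Component$fdr, direct$fdr[direct$kind == "Component"])
})

test_that("the fixture transport reproduces written records exactly", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "cmp1"))
  recs <- enrichment_records(kind = "KEGG", term_id = c("map1", "map2"),
                             description = c("alpha", "beta"),
                             fdr = c(0.001, 0.04),
                             genes = list(c("G1", "G2"), "G3"))
  write_enrichment_tsv(recs, file.path(td, "cmp1", "UP_KEGG.tsv"))
  transport <- string_transport_fixture(td)
  payload <- transport(list(label = "cmp1", direction = "UP"))
  parsed <- parse_enrichment_payload(payload)
  expect_identical(parsed$term_id, recs$term_id)
  expect_identical(parsed$fdr, recs$fdr)
  expect_identical(parsed$genes, recs$genes)
  expect_error(transport(list(label = "nope", direction = "UP")), "no fixture")
})
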