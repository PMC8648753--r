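recs_of <- function(kind, ids, fdrs, genes, descs = ids) {
  enrichment_records(kind = kind, term_id = ids, description = descs,
                     fdr = fdrs, genes = genes)
}

test_that("a term in both directions keeps the lowest FDR and the gene union", {
  up <- recs_of("KEGG", "T", 0.01, list(c("A", "B")))
  down <- recs_of("KEGG", "T", 0.002, list("C"))
  merged <- merge_directions(up, down)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$fdr, 0.002)
  expect_setequal(merged$genes[[1]], c("A", "B", "C"))
  expect_identical(merged$number_of_genes, 3L)
})

test_that("one-sided merges are identities and kind mismatches are errors", {
  up <- recs_of("KEGG", c("T1", "T2"), c(0.01, 0.02), list("A", "B"))
  expect_identical(as.data.frame(merge_directions(up, enrichment_records())),
                   as.data.frame(up))
  expect_identical(as.data.frame(merge_directions(enrichment_records(), up)),
                   as.data.frame(up))
  down <- recs_of("RCTM", "T1", 0.001, list("C"))
  expect_error(merge_directions(up, down), "different kinds")
})

test_that("merged FDRs equal an elementwise-min oracle on random overlaps", {
  withr::local_seed(5)
  for (rep in 1:20) {
    ids_up <- sample(sprintf("T%02d", 1:12), sample(3:10, 1))
    ids_down <- sample(sprintf("T%02d", 1:12), sample(3:10, 1))
    up <- recs_of("Process", ids_up, signif(stats::runif(length(ids_up), 0, 0.05), 6),
                  replicate(length(ids_up), sprintf("G%d", sample(20, 3)),
                            simplify = FALSE))
    down <- recs_of("Process", ids_down, signif(stats::runif(length(ids_down), 0, 0.05), 6),
                    replicate(length(ids_down), sprintf("G%d", sample(20, 3)),
                              simplify = FALSE))
    merged <- merge_directions(up, down)
    expect_setequal(merged$term_id, union(ids_up, ids_down))
    for (t in merged$term_id) {
      candidates <- c(up$fdr[up$term_id == t], down$fdr[down$term_id == t])
      expect_identical(merged$fdr[merged$term_id == t], min(candidates))
    }
  }
})

test_that("single-condition terms carry the n/a sentinel and their genes in all_genes", {
  cmp <- list(make_comparison("c1", "KEGG",
                              list(list(term_id = "T", fdr = 0.01,
                                        genes = c("A", "B")))))
  s <- build_summary(cmp, "KEGG")
  expect_identical(s$occurrence, 1L)
  expect_identical(s$common_status, "single")
  expect_identical(s$all_genes[[1]], c("A", "B"))
})

test_that("disjoint gene sets across comparisons yield the no-common sentinel", {
  cmp <- list(
    make_comparison("c1", "KEGG", list(list(term_id = "T", fdr = 0.01,
                                            genes = c("A", "B")))),
    make_comparison("c2", "KEGG", list(list(term_id = "T", fdr = 0.02,
                                            genes = c("C"))))
  )
  s <- build_summary(cmp, "KEGG")
  expect_identical(s$occurrence, 2L)
  expect_identical(s$common_status, "no_common")
  expect_identical(s$common_genes[[1]], character(0))
  expect_identical(s$min_fdr, 0.01)
  expect_identical(s$all_genes[[1]], c("A", "B", "C"))
})

test_that("summary fields equal a brute-force set-algebra oracle on planted fixtures", {
  fixture <- local_fixture(n_comparisons = 4, n_terms = 8, seed = 13)
  report <- suppressMessages(run_analysis(
    run_config(fixture$de, fixture$out, offline_fixture_dir = fixture$fx$dir),
    quiet = TRUE))
  for (kind in STRING_KINDS) {
    oracle <- oracle_aggregate(fixture$fx$dir, report$labels, kind)
    s <- report$aggregates[[kind]]$summary
    expect_setequal(s$term_id, names(oracle))
    for (i in seq_len(nrow(s))) {
      o <- oracle[[s$term_id[[i]]]]
      expect_identical(s$min_fdr[[i]], o$min_fdr)
      expect_identical(s$occurrence[[i]], o$occurrence)
      expect_identical(s$all_genes[[i]], o$all_genes)
      if (s$common_status[[i]] == "genes") {
        expect_identical(s$common_genes[[i]], o$common_genes)
      } else if (s$common_status[[i]] == "no_common") {
        expect_length(o$common_genes, 0)
        expect_gte(o$occurrence, 2)
      } else {
        expect_identical(o$occurrence, 1L)
      }
    }
  }
})

test_that("results rows hold the FDR where present and exactly 1 where absent", {
  cmp <- list(
    make_comparison("c1", "KEGG", list(list(term_id = "T", fdr = 0.01,
                                            genes = "A"))),
    make_comparison("c2", "KEGG", list(list(term_id = "U", fdr = 0.002,
                                            genes = "B"))),
    make_comparison("c3", "KEGG", list(list(term_id = "U", fdr = 0.03,
                                            genes = "B")))
  )
  r <- build_results(cmp, "KEGG")
  expect_identical(attr(r, "comparisons"), c("c1", "c2", "c3"))
  row_t <- r[r$term_id == "T", ]
  expect_identical(unlist(row_t[c("c1", "c2", "c3")], use.names = FALSE),
                   c(0.01, 1, 1))
  row_u <- r[r$term_id == "U", ]
  expect_identical(unlist(row_u[c("c1", "c2", "c3")], use.names = FALSE),
                   c(1, 0.002, 0.03))
})

test_that("summary and results stay mutually consistent on fixtures", {
  fixture <- local_fixture(n_comparisons = 5, n_terms = 10, seed = 23)
  report <- suppressMessages(run_analysis(
    run_config(fixture$de, fixture$out, offline_fixture_dir = fixture$fx$dir),
    quiet = TRUE))
  alpha <- 0.05
  for (kind in names(report$aggregates)) {
    s <- report$aggregates[[kind]]$summary
    r <- report$aggregates[[kind]]$results
    labs <- attr(r, "comparisons")
    expect_identical(s$term_id, r$term_id)
    for (i in seq_len(nrow(s))) {
      cells <- unlist(r[i, labs], use.names = FALSE)
      expect_identical(s$min_fdr[[i]], min(cells))
      expect_identical(s$occurrence[[i]], sum(cells < alpha))
      expect_gte(sum(cells < 1), 1L)
    }
  }
})

test_that("duplicate comparison labels are refused", {
  cmp <- list(
    make_comparison("c1", "KEGG", list(list(term_id = "T", fdr = 0.01, genes = "A"))),
    make_comparison("c1", "KEGG", list(list(term_id = "U", fdr = 0.01, genes = "B")))
  )
  expect_error(build_summary(cmp, "KEGG"), "duplicate comparison labels")
  expect_error(build_results(cmp, "KEGG"), "duplicate comparison labels")
})

test_that("adding a comparison is monotone for every summary field", {
  withr::local_seed(31)
  base <- lapply(1:4, function(i) {
    make_comparison(paste0("c", i), "KEGG", lapply(
      sample(sprintf("T%d", 1:6), 4),
      function(t) list(term_id = t, fdr = signif(stats::runif(1, 0, 0.05), 6),
                       genes = sprintf("G%d", sample(12, 4)))
    ))
  })
  extra <- make_comparison("c5", "KEGG", lapply(
    sprintf("T%d", 1:6),
    function(t) list(term_id = t, fdr = signif(stats::runif(1, 0, 0.05), 6),
                     genes = sprintf("G%d", sample(12, 4)))
  ))
  s4 <- build_summary(base, "KEGG")
  s5 <- build_summary(c(base, list(extra)), "KEGG")
  for (t in s4$term_id) {
    i4 <- match(t, s4$term_id); i5 <- match(t, s5$term_id)
    expect_gte(s5$occurrence[[i5]], s4$occurrence[[i4]])
    expect_lte(s5$min_fdr[[i5]], s4$min_fdr[[i4]])
    expect_true(all(s4$all_genes[[i4]] %in% s5$all_genes[[i5]]))
    if (s4$common_status[[i4]] == "genes" && s5$common_status[[i5]] == "genes") {
      expect_true(all(s5$common_genes[[i5]] %in% s4$common_genes[[i4]]))
    }
  }
})

test_that("UP_ONLY equals UP_DOWN_SEPARATE when DOWN lists are empty", {
  td <- withr::local_tempdir()
  withr::local_seed(17)
  for (lab in c("cmpA", "cmpB")) {
    dir.create(file.path(td, lab))
    recs <- recs_of("KEGG", sprintf("T%d", 1:4),
                    signif(stats::runif(4, 0, 0.04), 6),
                    replicate(4, sprintf("G%d", sample(10, 3)), simplify = FALSE))
    write_enrichment_tsv(recs, file.path(td, lab, "UP_KEGG.tsv"))
  }
  transport <- string_transport_fixture(td)
  sets <- structure(list(up = c("G1", "G2"), down = character(0),
                         all = c("G1", "G2")), class = "gene_sets")
  run_mode <- function(mode) {
    per_dir <- unlist(lapply(c("cmpA", "cmpB"), function(lab) {
      fetch_enrichment(sets, analysis_settings(mode = mode), transport, lab)
    }), recursive = FALSE)
    aggregate_enrichment(per_dir)
  }
  both <- run_mode("UP_DOWN_SEPARATE")
  up_only <- run_mode("UP_ONLY")
  expect_identical(as.data.frame(both$KEGG$summary),
                   as.data.frame(up_only$KEGG$summary))
  expect_identical(as.data.frame(both$KEGG$results),
                   as.data.frame(up_only$KEGG$results))
})

test_that("summary and results tables round-trip through TSV", {
  fixture <- local_fixture(n_comparisons = 3, n_terms = 10, seed = 41,
                           kinds = "Process")
  report <- suppressMessages(run_analysis(
    run_config(fixture$de, fixture$out, offline_fixture_dir = fixture$fx$dir),
    quiet = TRUE))
  s <- report$aggregates$Process$summary
  r <- report$aggregates$Process$results
  sf <- file.path(fixture$root, "summary_Process.tsv")
  rf <- file.path(fixture$root, "results_Process.tsv")
  write_summary(s, sf)
  write_results(r, rf)
  expect_identical(as.data.frame(read_summary(sf)), as.data.frame(s))
  expect_identical(as.data.frame(read_results(rf)), as.data.frame(r))
})

test_that("sentinels serialize as their literal texts", {
  cmp <- list(
    make_comparison("c1", "KEGG", list(
      list(term_id = "S", fdr = 0.01, genes = "A"),
      list(term_id = "N", fdr = 0.02, genes = "X")
    )),
    make_comparison("c2", "KEGG", list(
      list(term_id = "N", fdr = 0.03, genes = "Y")
    ))
  )
  s <- build_summary(cmp, "KEGG")
  f <- file.path(withr::local_tempdir(), "summary_KEGG.tsv")
  write_summary(s, f)
  cells <- vapply(strsplit(readLines(f)[-1], "\t"), `[[`, character(1), 6)
  expect_true("n/a: just one condition" %in% cells)
  expect_true("No common gene" %in% cells)
})
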