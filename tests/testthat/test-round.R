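# The round orchestrator, merge-back, and the command-line interface.

round_fixture <- function(seed = 20) {
  cfg <- fixture_config(n_genes = 25, n_edges = 80, corpus_size = 400,
                        belief_distribution = "uniform")
  kg <- generate_kg(cfg, seed = seed)
  gen <- generate_corpus(kg, cfg, seed = seed)
  list(cfg = cfg, kg = kg, gen = gen)
}

test_that("a round produces a manifest whose counts recount correctly", {
  fx <- round_fixture()
  out <- withr::local_tempdir()
  man <- run_round(fx$kg, fx$gen$corpus, out, k = 10, round_id = "r1",
                   query_config = corpus_query_config(belief_threshold = 0.5))
  expect_length(man$genes_selected, 10)
  expect_true(file.exists(file.path(out, "r1_manifest.json")))
  # independent recount of each filter stage
  pre <- preprocess(fx$kg)
  genes <- select_round(rank_genes(pre), 10)
  expect_equal(man$genes_selected, genes)
  matched <- query_corpus(fx$gen$corpus, genes)
  expect_equal(man$n_matched, nrow(matched))
  after_novel <- filter_novel(matched, fx$kg)
  expect_equal(man$n_after_novelty_filter, nrow(after_novel))
  after_belief <- filter_belief(after_novel, 0.5)
  expect_equal(man$n_after_belief_filter, nrow(after_belief))
  cand <- assemble_statements(after_belief)$edges
  expect_equal(man$n_candidate_edges, nrow(cand))
  expect_equal(sum(unlist(man$statements_per_gene)), nrow(cand))
})

test_that("reruns with the same inputs are byte-identical", {
  fx <- round_fixture()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_round(fx$kg, fx$gen$corpus, d1, k = 8, round_id = "rr")
  run_round(fx$kg, fx$gen$corpus, d2, k = 8, round_id = "rr")
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "rr_manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), info = f)
  }
})

test_that("excluding round-one genes surfaces new genes in round two", {
  fx <- round_fixture()
  d <- withr::local_tempdir()
  m1 <- run_round(fx$kg, fx$gen$corpus, d, k = 5, round_id = "r1")
  m2 <- run_round(fx$kg, fx$gen$corpus, d, k = 5, round_id = "r2",
                  exclude = m1$genes_selected)
  expect_length(intersect(m1$genes_selected, m2$genes_selected), 0)
})

test_that("merge adds correct and corrected rows, skips the rest", {
  rows <- data.frame(
    uuid = c("u1", "u2", "u3", "u4"),
    gene = "HGNC:A", reference = c("1", "2", "3", "4"), evidence = "ev",
    bel = c("p(HGNC:A) increases p(HGNC:B)",
            "p(HGNC:A) decreases p(HGNC:C)",
            "p(HGNC:A) increases p(HGNC:D)",
            "p(HGNC:A) increases p(HGNC:E)"),
    checked = TRUE,
    correct = c(TRUE, FALSE, FALSE, FALSE),
    changed = c(FALSE, TRUE, FALSE, TRUE),
    error_type = NA_character_,
    corrected_bel = c("", "p(HGNC:C) decreases p(HGNC:A)", "",
                      "p(HGNC:A) wibble p(HGNC:E)"),
    curator = "c1", stringsAsFactors = FALSE
  )
  res <- merge_curated(bel_kg(), rows)
  expect_equal(res$n_merged, 2)
  expect_equal(kg_n_edges(res$kg), 2)
  # u3 (uncorrectable) absent; u4 unparseable -> error record
  expect_equal(res$errors$uuid, "u4")
  expect_false(any(res$kg$edges$citation == "3"))
  expect_true("p(HGNC:C)" %in% res$kg$edges$subject)
})

test_that("the closed loop grows the graph by exactly the recovered statements", {
  fx <- round_fixture(seed = 23)
  out <- withr::local_tempdir()
  man <- run_round(fx$kg, fx$gen$corpus, out, k = 15, round_id = "r1",
                   query_config = corpus_query_config(belief_threshold = 0))
  sheets <- unlist(man$sheets)
  filled <- do.call(rbind, lapply(sheets, simulate_curator,
                                  truth = fx$gen$truth, seed = 23))
  rows <- ingest_sheet(filled)$rows
  res <- merge_curated(bel_kg(), rows)
  cls <- classify_rows(rows)
  # merged count equals recoverable rows minus exact-duplicate statements
  expect_equal(res$n_merged, sum(cls %in% c("correct", "changed")))
  expect_lte(kg_n_edges(res$kg), res$n_merged)
  expect_equal(nrow(res$errors), 0)
})

# ---- command-line interface ------------------------------------------------

test_that("qc check exits nonzero iff a required annotation is missing", {
  kg <- kg_add_edge(bel_kg(), bel_entity("protein", "HGNC", "A"),
                    bel_entity("protein", "HGNC", "B"), "increases",
                    evidence = "e", citation = "1",
                    annotations = c(Confidence = "High"))
  good <- withr::local_tempfile(fileext = ".bel")
  write_bel_script(kg, good)
  expect_equal(run_cli("qc", "check", "--required", "Confidence", good)$status, 0L)

  kg2 <- kg_add_edge(kg, bel_entity("protein", "HGNC", "B"),
                     bel_entity("protein", "HGNC", "C"), "decreases",
                     evidence = "e2", citation = "2")
  bad <- withr::local_tempfile(fileext = ".bel")
  write_bel_script(kg2, bad)
  res <- run_cli("qc", "check", "--required", "Confidence", bad)
  expect_equal(res$status, 1L)
  expect_match(res$output, "missing required")
})

test_that("sheets validate exits 1 on findings and 0 on clean sheets", {
  cfg <- fixture_config(n_genes = 10, n_edges = 30, corpus_size = 60)
  kg <- generate_kg(cfg, seed = 30)
  gen <- generate_corpus(kg, cfg, seed = 30)
  cand <- assemble_statements(query_corpus(gen$corpus,
                                           rank_genes(preprocess(kg))$gene_key))$edges
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  filled <- simulate_curator(paths[[1]], gen$truth, seed = 30)
  clean <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(filled, clean, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(run_cli("sheets", "validate", clean)$status, 0L)
  filled$checked[1] <- ""
  filled$changed[1] <- "x"; filled$correct[1] <- ""
  dirty <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(filled, dirty, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- run_cli("sheets", "validate", dirty)
  expect_equal(res$status, 1L)
  expect_match(res$output, "rule1")
})

test_that("missing inputs give the I/O exit code", {
  expect_equal(run_cli("qc", "check", "--required", "Confidence",
                       "/no/such/file.bel")$status, 2L)
  expect_equal(run_cli("frobnicate")$status, 2L)
})
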