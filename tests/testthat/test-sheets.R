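# Sheet generation, the marking protocol, and row classification.

make_candidates <- function() {
  corpus <- make_corpus(list(
    list(type = "activation", s = "AAA", o = "BBB", citation = "2"),
    list(type = "phosphorylation", s = "AAA", o = "CCC", citation = "1",
         mod_residue = "Thr", mod_position = "231"),
    list(type = "inhibition", s = "DDD", o = "AAA", citation = "3"),
    list(type = "activation", s = "DDD", o = "BBB", citation = "1")
  ))
  corpus <- query_corpus(corpus, c("HGNC:AAA", "HGNC:DDD"))
  assemble_statements(corpus)$edges
}

test_that("one sheet per gene with rows ordered by citation then uuid", {
  cand <- make_candidates()
  dir <- withr::local_tempdir()
  paths <- generate_sheets(cand, dir, round_id = "r1")
  expect_setequal(names(paths), c("HGNC:AAA", "HGNC:DDD"))
  aaa <- utils::read.delim(paths[["HGNC:AAA"]], colClasses = "character")
  # activation 1 row + phosphorylation 2 rows + inhibition (primary gene AAA)
  expect_equal(nrow(aaa), 4)
  expect_equal(aaa$reference, sort(aaa$reference))
  # decision columns empty
  expect_true(all(aaa$checked == "" & aaa$correct == "" & aaa$changed == ""))
  # multi-edge statement duplicates provenance across its rows
  phos <- aaa[aaa$uuid == cand$uuid[grepl("hasVariant", cand$bel)][1], ]
  expect_equal(nrow(phos), 2)
  expect_equal(length(unique(phos$evidence)), 1)
  expect_equal(length(unique(phos$reference)), 1)
})

test_that("sheet generation is byte-for-byte deterministic", {
  cand <- make_candidates()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_sheets(cand, d1, round_id = "r1")
  p2 <- generate_sheets(cand[sample(nrow(cand)), ], d2, round_id = "r1")
  for (g in names(p1)) {
    expect_identical(readLines(p1[[g]]), readLines(p2[[g]]), info = g)
  }
})

test_that("filled marks are parsed and the protocol rules enforced", {
  cand <- make_candidates()
  dir <- withr::local_tempdir()
  paths <- generate_sheets(cand, dir, combined = TRUE)
  sheet <- utils::read.delim(paths[[1]], colClasses = "character")
  sheet$checked <- c("x", "X", "", "x", "x")
  sheet$correct <- c("x", "", "", "", "")
  sheet$changed <- c("", "x", "x", "", "")     # row 3 changed without checked
  sheet$error_type <- c("", "ner_wrong_entity", "", "", "")
  res <- ingest_sheet(sheet)
  expect_equal(nrow(res$findings), 1)
  expect_equal(res$findings$rule, "rule1")
  expect_equal(res$findings$row, 3L)
  expect_equal(nrow(res$rows), 4)
  expect_equal(classify_rows(res$rows), c("correct", "changed", "uncorrectable", "uncorrectable"))
})

test_that("both-marked, bad-vocabulary and bad-mark rows are findings", {
  cand <- make_candidates()
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  sheet <- utils::read.delim(paths[[1]], colClasses = "character")
  sheet$checked <- "x"
  sheet$correct <- c("x", "yes", "", "", "")
  sheet$changed <- c("x", "", "x", "", "")
  sheet$error_type <- c("", "", "typo_error", "", "")
  res <- ingest_sheet(sheet)
  expect_setequal(res$findings$rule, c("rule2", "mark-syntax", "vocabulary"))
  expect_equal(nrow(res$rows), 2)
})

test_that("error_type on a correct row violates the protocol", {
  cand <- make_candidates()
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  sheet <- utils::read.delim(paths[[1]], colClasses = "character")
  sheet$checked[1] <- "x"; sheet$correct[1] <- "x"
  sheet$error_type[1] <- "ner_wrong_entity"
  res <- ingest_sheet(sheet)
  expect_true("rule3" %in% res$findings$rule)
})

test_that("curator-added rows must be changed-only and share provenance", {
  cand <- make_candidates()
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  sheet <- utils::read.delim(paths[[1]], colClasses = "character")
  sheet$checked <- "x"; sheet$correct <- "x"
  extra_ok <- sheet[1, ]
  extra_ok$bel <- "p(HGNC:AAA) increases p(HGNC:ZZZ)"
  extra_ok$correct <- ""; extra_ok$changed <- "x"
  extra_bad <- extra_ok
  extra_bad$bel <- "p(HGNC:AAA) decreases p(HGNC:ZZZ)"
  extra_bad$changed <- ""; extra_bad$correct <- "x"
  alien <- extra_ok
  alien$uuid <- "not-a-known-uuid"
  filled <- rbind(sheet, extra_ok, extra_bad, alien)
  res <- ingest_sheet(filled, machine_rows = sheet[, c("uuid", "bel")])
  expect_setequal(res$findings$rule, c("rule5", "provenance"))
  expect_equal(nrow(res$rows), nrow(sheet) + 1)
})

test_that("unknown sheet columns are a hard error", {
  cand <- make_candidates()
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  sheet <- utils::read.delim(paths[[1]], colClasses = "character")
  sheet$surprise <- "1"
  expect_error(ingest_sheet(sheet), "unknown column")
})

test_that("a planted-violation sheet yields exactly the planted findings", {
  withr::local_seed(17)
  cfg <- fixture_config(n_genes = 25, n_edges = 60, corpus_size = 150)
  kg <- generate_kg(cfg, seed = 17)
  gen <- generate_corpus(kg, cfg, seed = 17)
  cand <- assemble_statements(query_corpus(gen$corpus, rank_genes(preprocess(kg))$gene_key))$edges
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  filled <- simulate_curator(paths[[1]], gen$truth, seed = 17)
  n <- nrow(filled)
  plant <- sort(sample(n, 10))
  kinds <- rep(c("unchecked_mark", "both", "badvocab"), length.out = 10)
  for (i in seq_along(plant)) {
    r <- plant[i]
    if (kinds[i] == "unchecked_mark") {
      filled$checked[r] <- ""
      filled$changed[r] <- "x"; filled$correct[r] <- ""
    } else if (kinds[i] == "both") {
      filled$correct[r] <- "x"; filled$changed[r] <- "x"
      filled$error_type[r] <- ""
    } else {
      filled$changed[r] <- "x"; filled$correct[r] <- ""
      filled$error_type[r] <- "made_up_code"
    }
  }
  res <- ingest_sheet(filled)
  expect_equal(sort(unique(res$findings$row)), plant)
  expect_equal(nrow(res$rows), n - 10)
})

test_that("classification matches the brute-force truth table", {
  grid <- expand.grid(checked = c(TRUE, FALSE), correct = c(TRUE, FALSE),
                      changed = c(TRUE, FALSE))
  grid <- grid[!(grid$correct & grid$changed), ]
  grid <- grid[grid$checked | (!grid$correct & !grid$changed), ]
  got <- classify_rows(grid)
  oracle <- apply(grid, 1, function(r) {
    if (r[["correct"]]) "correct"
    else if (r[["changed"]]) "changed"
    else if (r[["checked"]]) "uncorrectable"
    else "unchecked"
  })
  expect_equal(got, unname(oracle))
  # total and mutually exclusive by construction of the truth table
  expect_true(all(got %in% c("correct", "changed", "uncorrectable", "unchecked")))
})

test_that("generate then ingest round-trips machine rows intact", {
  cand <- make_candidates()
  paths <- generate_sheets(cand, withr::local_tempdir(), combined = TRUE)
  res <- ingest_sheet(paths[[1]])
  expect_equal(nrow(res$findings), 0)
  expect_setequal(paste(res$rows$uuid, res$rows$bel), paste(cand$uuid, cand$bel))
  idx <- match(paste(res$rows$uuid, res$rows$bel), paste(cand$uuid, cand$bel))
  expect_equal(res$rows$reference, cand$citation[idx])
  expect_equal(res$rows$evidence, cand$evidence[idx])
})
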