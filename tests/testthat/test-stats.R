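# Curation quality statistics.

# Build validated-row data frames directly (the post-ingest layout).
rows_from_counts <- function(correct, changed, uncorrectable, unchecked = 0,
                             gene = "HGNC:G1") {
  n <- correct + changed + uncorrectable + unchecked
  data.frame(
    uuid = sprintf("u%05d", seq_len(n)),
    gene = gene,
    reference = "1", evidence = "e", bel = "p(HGNC:A) increases p(HGNC:B)",
    checked = rep(c(TRUE, TRUE, TRUE, FALSE),
                  c(correct, changed, uncorrectable, unchecked)),
    correct = rep(c(TRUE, FALSE, FALSE, FALSE),
                  c(correct, changed, uncorrectable, unchecked)),
    changed = rep(c(FALSE, TRUE, FALSE, FALSE),
                  c(correct, changed, uncorrectable, unchecked)),
    error_type = NA_character_, corrected_bel = "", curator = "c1",
    stringsAsFactors = FALSE
  )
}

test_that("summary reproduces the campaign evaluation arithmetic", {
  rows <- rows_from_counts(917, 1454, 618)
  rep <- summarize_curation(rows)
  expect_equal(rep$n_evaluated, 2989)
  expect_equal(rep$n_correct + rep$n_changed + rep$n_uncorrectable, rep$n_evaluated)
  expect_equal(round(rep$pct_correct, 1), 30.7)
  expect_equal(round(rep$pct_changed, 1), 48.6)
  expect_equal(round(rep$pct_uncorrectable, 1), 20.7)
  expect_equal(round(rep$recovery_pct, 1), 79.3)
  expect_equal(rep$pct_correct + rep$pct_changed + rep$pct_uncorrectable, 100)
})

test_that("all-correct rows give 100% accuracy and recovery", {
  rep <- summarize_curation(rows_from_counts(25, 0, 0))
  expect_equal(rep$pct_correct, 100)
  expect_equal(rep$recovery_pct, 100)
})

test_that("unchecked rows never enter denominators; zero evaluated is flagged", {
  rep <- summarize_curation(rows_from_counts(10, 5, 5, unchecked = 80))
  expect_equal(rep$n_evaluated, 20)
  expect_equal(rep$pct_correct, 50)
  empty <- summarize_curation(rows_from_counts(0, 0, 0, unchecked = 4))
  expect_true(empty$undefined)
  expect_equal(empty$n_evaluated, 0)
  expect_true(is.na(empty$pct_correct) && !is.nan(empty$pct_correct))
})

test_that("summary is permutation-invariant over rows", {
  rows <- rbind(rows_from_counts(9, 4, 3, gene = "HGNC:G1"),
                rows_from_counts(2, 8, 5, gene = "HGNC:G2"))
  rep1 <- summarize_curation(rows)
  withr::local_seed(5)
  rep2 <- summarize_curation(rows[sample(nrow(rows)), ])
  expect_equal(rep1[setdiff(names(rep1), "per_gene")],
               rep2[setdiff(names(rep2), "per_gene")])
  expect_equal(rep1$per_gene[order(rep1$per_gene$gene_key), ],
               rep2$per_gene[order(rep2$per_gene$gene_key), ])
})

test_that("per-gene accuracy estimates recover a planted rate", {
  withr::local_seed(2024)
  p_correct <- 0.35
  n <- 200
  genes <- sprintf("HGNC:G%02d", 1:10)
  rows <- do.call(rbind, lapply(genes, function(g) {
    k <- stats::rbinom(1, n, p_correct)
    rows_from_counts(k, n - k, 0, gene = g)
  }))
  rep <- summarize_curation(rows)
  est <- mean(rep$per_gene$accuracy_pct) / 100
  half_width <- 1.96 * sqrt(p_correct * (1 - p_correct) / (n * length(genes)))
  expect_lt(abs(est - p_correct), half_width * 2)
})

test_that("throughput matches the campaign figure and scales linearly", {
  expect_equal(round(throughput(17002, 80), 2), 3.54)
  expect_equal(throughput(60, 1), 1)
  expect_error(throughput(100, 0), "positive")
  withr::local_seed(8)
  for (rep_i in 1:20) {
    n <- sample(1000:20000, 1); h <- stats::runif(1, 1, 100)
    expect_equal(throughput(n, h / 2), 2 * throughput(n, h))
  }
})

test_that("error profile counts plants exactly and fractions stay below one", {
  rows <- rows_from_counts(5, 4, 2)
  rows$error_type[rows$changed][1:3] <- "ner_wrong_entity"
  rows$error_type[rows$changed][4] <- "subject_object_swap"
  prof <- error_profile(rows)
  expect_equal(prof$error_type, c("ner_wrong_entity", "subject_object_swap"))
  expect_equal(prof$count, c(3L, 1L))
  expect_equal(prof$fraction, c(3, 1) / 6)
  expect_lte(sum(prof$fraction), 1)
  expect_equal(nrow(error_profile(rows_from_counts(3, 0, 0))), 0)
})

test_that("group comparison matches the closed-form t statistic", {
  acc <- stats::setNames(seq(10, 100, length.out = 10), sprintf("g%02d", 1:10))
  effort <- stats::setNames(c(5.1, 4.8, 5.6, 5.0, 4.4, 2.2, 2.9, 2.4, 2.0, 2.6),
                            sprintf("g%02d", 1:10))
  res <- compare_groups(acc, k = 5, per_gene_effort = effort, var_equal = TRUE)
  top <- effort[c("g10", "g09", "g08", "g07", "g06")]
  bottom <- effort[c("g01", "g02", "g03", "g04", "g05")]
  sp2 <- (4 * stats::var(top) + 4 * stats::var(bottom)) / 8
  t_oracle <- (mean(top) - mean(bottom)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 8)
})

test_that("identical effort distributions give t near zero, p near one", {
  acc <- stats::setNames(1:10, sprintf("g%02d", 1:10))
  effort <- stats::setNames(rep(c(3, 4, 5, 4, 3), 2), sprintf("g%02d", 1:10))
  res <- compare_groups(acc, k = 5, per_gene_effort = effort)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("a planted effort gap is detected", {
  withr::local_seed(99)
  genes <- sprintf("g%02d", 1:40)
  acc <- stats::setNames(c(stats::runif(20, 60, 95), stats::runif(20, 5, 40)), genes)
  # high-accuracy genes curate ~1.5 min faster on average
  effort <- stats::setNames(numeric(40), genes)
  ord <- order(-acc)
  effort[genes[ord[1:20]]] <- stats::rnorm(20, 2.0, 0.5)
  effort[genes[ord[21:40]]] <- stats::rnorm(20, 3.5, 0.5)
  res <- compare_groups(acc, k = 20, per_gene_effort = effort)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$mean_top, res$mean_bottom)
})

test_that("group comparison rejects undersized groups", {
  acc <- stats::setNames(1:6, sprintf("g%d", 1:6))
  eff <- stats::setNames(rep(1, 6), sprintf("g%d", 1:6))
  expect_error(compare_groups(acc, k = 1, per_gene_effort = eff), "at least 2")
  expect_error(compare_groups(acc, k = 4, per_gene_effort = eff), "half")
})
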