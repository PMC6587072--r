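# One curation round end-to-end, and merging of curated rows back into
# the knowledge graph.

#' Run one rational-enrichment round
#'
#' Chains the workflow stages: preprocess the graph to its causal
#' gene-level core, rank genes by ascending information density, select
#' the `k` highest-priority genes (excluding genes from earlier rounds),
#' query the statement corpus for them, drop statements already curated in
#' the graph, drop low-belief statements, assemble the survivors into
#' candidate BEL edges and write one curation sheet per gene. A JSON
#' manifest records the selected genes, per-stage attrition counts and
#' statements per gene, so that a manifest plus the seed reproduces the
#' round byte-for-byte.
#'
#' @param kg the curated [bel_kg()] (un-preprocessed)
#' @param corpus a [bel_corpus]
#' @param out_dir output directory for sheets and manifest
#' @param k genes per round (default 30)
#' @param round_id round identifier
#' @param exclude gene keys already handled in earlier rounds
#' @param query_config a [corpus_query_config()]
#' @param policy an [assembly_policy()]
#' @param pre_config a [preprocess_config()]
#' @return the manifest, invisibly (a list; also written to
#'   `out_dir/<round_id>_manifest.json`)
#' @export
run_round <- function(kg, corpus, out_dir, k = 30L, round_id = "round-1",
                      exclude = character(),
                      query_config = corpus_query_config(),
                      policy = assembly_policy(),
                      pre_config = preprocess_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pre <- preprocess(kg, pre_config)
  ranked <- rank_genes(pre, exclude = exclude)
  genes <- select_round(ranked, k)
  matched <- query_corpus(corpus, genes)
  after_novel <- if (query_config$exclude_existing) {
    filter_novel(matched, kg, policy)
  } else {
    matched
  }
  after_belief <- filter_belief(after_novel, query_config$belief_threshold)
  assembled <- assemble_statements(after_belief, policy)
  sheets <- generate_sheets(assembled$edges, out_dir, round_id = round_id)

  per_gene <- table(assembled$edges$gene)
  manifest <- list(
    round_id = round_id,
    k = k,
    genes_selected = genes,
    n_genes_ranked = nrow(ranked),
    n_corpus = nrow(corpus),
    n_matched = nrow(matched),
    n_after_novelty_filter = nrow(after_novel),
    n_after_belief_filter = nrow(after_belief),
    n_skipped_assembly = nrow(assembled$skips),
    n_candidate_edges = nrow(assembled$edges),
    statements_per_gene = as.list(per_gene),
    sheets = as.list(sheets)
  )
  manifest_path <- file.path(out_dir, sprintf("%s_manifest.json", round_id))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(manifest, "candidates") <- assembled$edges
  invisible(manifest)
}

#' Merge curated rows back into a knowledge graph
#'
#' Correct rows contribute their machine statement; changed rows
#' contribute the curator's corrected statement; uncorrectable and
#' unchecked rows are excluded. Statements are parsed as BEL and appended
#' with the row's reference and evidence as provenance. An unparseable
#' corrected statement produces a row-level error record and the row is
#' skipped — merging never fails wholesale.
#'
#' @param kg a [bel_kg()] to extend (may be empty)
#' @param rows validated rows from [ingest_sheet()]
#' @return list with `kg` (the grown graph), `n_merged`, and `errors`
#'   (data frame: row, uuid, message)
#' @export
merge_curated <- function(kg, rows) {
  errors <- data.frame(row = integer(0), uuid = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  cls <- classify_rows(rows)
  n_merged <- 0L
  for (i in seq_len(nrow(rows))) {
    stmt_text <- switch(cls[i],
      correct = rows$bel[i],
      changed = rows$corrected_bel[i],
      NA_character_
    )
    if (is.na(stmt_text)) next
    parsed <- tryCatch(parse_bel_statement(stmt_text), error = function(e) e)
    if (inherits(parsed, "error")) {
      errors <- rbind(errors, data.frame(
        row = i, uuid = rows$uuid[i],
        message = conditionMessage(parsed), stringsAsFactors = FALSE
      ))
      next
    }
    kg <- kg_add_edge(
      kg, parsed$subject, parsed$object, parsed$relation,
      evidence = rows$evidence[i], citation = rows$reference[i],
      subject_activity = parsed$subject_activity,
      object_activity = parsed$object_activity
    )
    n_merged <- n_merged + 1L
  }
  list(kg = kg, n_merged = n_merged, errors = errors)
}
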