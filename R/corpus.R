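# Machine-extracted statement corpus: reader, gene query, and the novelty
# and belief-score filters applied before curation.

STATEMENT_TYPES <- c(
  "activation", "inhibition", "phosphorylation", "other_modification",
  "complex_formation", "regulate_amount", "other"
)

CORPUS_COLS <- c(
  "uuid", "statement_type", "belief", "evidence", "citation", "readers",
  "negated", "subject", "object", "members", "mod_residue", "mod_position"
)

#' Corpus query configuration
#'
#' @param belief_threshold minimum belief score to keep (default 0.80;
#'   statements scoring strictly below are removed to raise precision)
#' @param exclude_existing drop statements whose canonical triple is
#'   already curated in the knowledge graph
#' @return a list of class `corpus_query_config`
#' @export
corpus_query_config <- function(belief_threshold = 0.80, exclude_existing = TRUE) {
  stopifnot(belief_threshold >= 0, belief_threshold <= 1)
  structure(
    list(belief_threshold = belief_threshold, exclude_existing = exclude_existing),
    class = "corpus_query_config"
  )
}

parse_grounding_json <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  jsonlite::fromJSON(s, simplifyVector = FALSE)
}

# candidate list -> character vector of canonical gene-style keys
candidate_keys <- function(grounding) {
  if (is.null(grounding)) return(character(0))
  cands <- grounding$candidates
  if (is.null(cands)) return(character(0))
  vapply(cands, function(c) {
    sprintf("%s:%s", toupper(c$namespace), c$identifier)
  }, character(1))
}

#' Read a statement corpus from TSV
#'
#' The corpus format is tab-separated with one machine-extracted relation
#' per row: `uuid`, `statement_type`, `belief` (0–1), `evidence`,
#' `citation`, `readers` (comma-separated source readers), `negated`
#' (true/false), `subject`/`object`/`members` (JSON groundings with a
#' `label` and a `candidates` list of namespace/identifier pairs), and
#' `mod_residue`/`mod_position` for modification statements. Malformed rows
#' (bad JSON, unknown statement type, out-of-range belief) are skipped with
#' a logged warning carrying the row index; they are reported in the
#' `skipped` attribute, never silently lost.
#'
#' @param path TSV file path
#' @return a data frame of class `bel_corpus` with parsed list columns
#'   `subject_cand`, `object_cand`, `members_cand`
#' @export
read_corpus <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                           quote = "", na.strings = NULL)
  missing_cols <- setdiff(CORPUS_COLS, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("corpus is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  as_corpus(raw)
}

# Validate and parse a raw character corpus data frame.
as_corpus <- function(raw) {
  n <- nrow(raw)
  keep <- logical(n)
  skipped <- empty_df(c("row", "message"))
  subject_cand <- vector("list", n)
  object_cand <- vector("list", n)
  members_cand <- vector("list", n)
  belief <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    msg <- NULL
    row <- raw[i, ]
    if (!row$statement_type %in% STATEMENT_TYPES) {
      msg <- sprintf("unknown statement_type '%s'", row$statement_type)
    } else {
      b <- suppressWarnings(as.numeric(row$belief))
      if (is.na(b) && nzchar(row$belief)) {
        msg <- "belief is not numeric"
      } else if (!is.na(b) && (b < 0 || b > 1)) {
        msg <- "belief outside [0, 1]"
      } else {
        belief[i] <- b
        parsed <- tryCatch({
          list(
            s = parse_grounding_json(row$subject),
            o = parse_grounding_json(row$object),
            m = parse_grounding_json(row$members)
          )
        }, error = function(e) e)
        if (inherits(parsed, "error")) {
          msg <- sprintf("malformed grounding JSON: %s", conditionMessage(parsed))
        } else {
          subject_cand[[i]] <- parsed$s
          object_cand[[i]] <- parsed$o
          members_cand[[i]] <- if (is.null(parsed$m)) list() else parsed$m
        }
      }
    }
    if (is.null(msg)) keep[i] <- TRUE
    else skipped <- rbind(skipped, data.frame(row = i, message = msg,
                                              stringsAsFactors = FALSE))
  }
  if (nrow(skipped)) {
    warning(sprintf("skipped %d malformed corpus row(s): rows %s",
                    nrow(skipped), paste(skipped$row, collapse = ", ")))
  }
  out <- raw[keep, CORPUS_COLS, drop = FALSE]
  out$belief <- belief[keep]
  out$negated <- tolower(out$negated) %in% c("true", "t", "1", "yes", "x")
  out$subject_cand <- I(subject_cand[keep])
  out$object_cand <- I(object_cand[keep])
  out$members_cand <- I(members_cand[keep])
  out$matched_genes <- I(vector("list", sum(keep)))
  out$gene <- rep(NA_character_, sum(keep))
  out$novelty_flag <- rep(NA_character_, sum(keep))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("bel_corpus", "data.frame")
  out
}

statement_gene_keys <- function(st, i) {
  unique(c(
    candidate_keys(st$subject_cand[[i]]),
    candidate_keys(st$object_cand[[i]]),
    unlist(lapply(st$members_cand[[i]], candidate_keys))
  ))
}

#' Query a corpus for statements mentioning prioritised genes
#'
#' A statement matches when any candidate grounding of its subject, object
#' or complex members equals a queried canonical gene key. Matched
#' statements are tagged with the matching gene(s); the first match (in
#' query order) becomes the primary `gene` used for sheet grouping.
#'
#' @param corpus a [read_corpus()] result
#' @param genes character vector of canonical gene keys
#' @return the matching subset of `corpus`
#' @export
query_corpus <- function(corpus, genes) {
  stopifnot(inherits(corpus, "bel_corpus"))
  if (!length(genes) || !nrow(corpus)) return(corpus[integer(0), , drop = FALSE])
  keep <- logical(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    keys <- statement_gene_keys(corpus, i)
    hits <- genes[genes %in% keys]
    if (length(hits)) {
      keep[i] <- TRUE
      corpus$matched_genes[[i]] <- hits
      corpus$gene[i] <- hits[1]
    }
  }
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical triple key implied by a corpus statement under a grounding
# policy; NA when ungroundable.
statement_triple_key <- function(st, i, policy) {
  type <- st$statement_type[i]
  rel <- switch(type,
    activation = "increases",
    inhibition = "decreases",
    phosphorylation = "increases",
    other_modification = "increases",
    regulate_amount = "regulates",
    complex_formation = "association",
    "association"
  )
  if (type == "complex_formation") {
    members <- lapply(st$members_cand[[i]], ground_candidates, policy = policy)
    members <- Filter(function(e) e$grounded, members)
    if (length(members) < 2) return(NA_character_)
    keys <- vapply(seq_along(members)[-1], function(j) {
      canonical_triple(members[[1]], members[[j]], "association")$key
    }, character(1))
    return(paste(sort(keys), collapse = " & "))
  }
  subj <- ground_candidates(st$subject_cand[[i]], policy)
  obj <- ground_candidates(st$object_cand[[i]], policy)
  if (!subj$grounded || !obj$grounded) return(NA_character_)
  canonical_triple(subj, obj, rel)$key
}

#' Remove statements already curated in the knowledge graph
#'
#' A statement is redundant when the canonical (gene-collapsed) triple of
#' its implied edge already exists in the graph — comparison is at gene
#' level, so e.g. a phosphorylation statement duplicates an existing
#' protein-level increase between the same genes. Statements with the same
#' entities but a different polarity are retained. Ungroundable statements
#' are retained and flagged (`novelty_flag = "ungroundable"`) for the
#' curator to decide.
#'
#' @param statements a [bel_corpus] subset
#' @param kg the un-preprocessed curated [bel_kg()]
#' @param policy grounding policy, see [assembly_policy()]
#' @return the novel subset
#' @export
filter_novel <- function(statements, kg, policy = assembly_policy()) {
  if (!nrow(statements)) return(statements)
  existing <- kg_triple_keys(kg)
  existing <- existing[!is.na(existing)]
  keep <- logical(nrow(statements))
  for (i in seq_len(nrow(statements))) {
    key <- statement_triple_key(statements, i, policy)
    if (is.na(key)) {
      keep[i] <- TRUE
      statements$novelty_flag[i] <- "ungroundable"
    } else if (statements$statement_type[i] == "complex_formation") {
      pair_keys <- strsplit(key, " & ", fixed = TRUE)[[1]]
      keep[i] <- !all(pair_keys %in% existing)
    } else {
      keep[i] <- !key %in% existing
    }
  }
  out <- statements[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter statements by belief score
#'
#' Keeps statements whose belief is at least the threshold; scores strictly
#' below are removed (a 0.80 threshold keeps a 0.80 statement). Missing
#' belief scores are treated as 0 — removed at any positive threshold —
#' and logged in the `dropped_missing` attribute.
#'
#' @param statements a [bel_corpus] subset
#' @param threshold belief threshold in \[0, 1\] (default 0.80)
#' @return the surviving subset
#' @export
filter_belief <- function(statements, threshold = 0.80) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!nrow(statements)) return(statements)
  belief <- statements$belief
  missing <- is.na(belief)
  belief[missing] <- 0
  keep <- belief >= threshold
  if (any(missing & !keep)) {
    attr(statements, "dropped_missing") <- which(missing & !keep)
  }
  out <- statements[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a corpus (or subset) as TSV
#'
#' @param corpus a [bel_corpus]
#' @param path output file
#' @return the path, invisibly
#' @export
write_corpus <- function(corpus, path) {
  utils::write.table(
    corpus[, CORPUS_COLS, drop = FALSE], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
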