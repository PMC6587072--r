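# Curation sheets: generation from assembled candidate edges, re-ingest of
# filled sheets under the six-rule marking protocol, and row classification.

SHEET_COLS <- c(
  "uuid", "gene", "reference", "evidence", "bel",
  "checked", "correct", "changed", "error_type", "corrected_bel", "curator"
)

#' Controlled vocabulary of curation error types
#'
#' The categories cover the errors commonly produced by automated reading
#' and assembly: wrong entity from named-entity recognition, swapped
#' subject/object, evidence containing no relation, missed negation,
#' direct/indirect confusion, missing modification, and grammatical or
#' structural problems. The vocabulary is closed but extensible via the
#' `extra` argument of [ingest_sheet()].
#'
#' @return character vector of error-type codes
#' @export
error_types <- function() {
  c(
    "ner_wrong_entity", "subject_object_swap", "no_relation_in_evidence",
    "negation_missed", "direct_indirect", "missing_modification",
    "grammar_structure", "other"
  )
}

#' Generate curation sheets from assembled candidate edges
#'
#' Writes one TSV sheet per gene (or a single combined sheet) with one row
#' per candidate BEL edge. Rows are ordered by citation then uuid; the
#' decision columns (`checked`, `correct`, `changed`, `error_type`,
#' `corrected_bel`, `curator`) are left empty for the curator. A statement
#' assembled into several edges contributes several rows sharing its uuid,
#' reference and evidence (provenance duplication). Output is byte-for-byte
#' deterministic given the same input.
#'
#' @param candidates the `edges` data frame from [assemble_statements()]
#' @param dir output directory (created if needed)
#' @param round_id identifier used as a file-name prefix
#' @param combined write a single sheet instead of one per gene
#' @return character vector of written file paths (named by gene)
#' @export
generate_sheets <- function(candidates, dir, round_id = "round-1",
                            combined = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sheet_df <- data.frame(
    uuid = candidates$uuid,
    gene = candidates$gene,
    reference = candidates$citation,
    evidence = flatten_ws(candidates$evidence),
    bel = candidates$bel,
    checked = "", correct = "", changed = "",
    error_type = "", corrected_bel = "", curator = "",
    stringsAsFactors = FALSE
  )
  sheet_df <- sheet_df[order(sheet_df$reference, sheet_df$uuid, sheet_df$bel,
                             method = "radix"), , drop = FALSE]
  groups <- if (combined) list(all = sheet_df) else split(sheet_df, sheet_df$gene)
  paths <- character(0)
  for (gene in sort(names(groups), method = "radix")) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", gene)
    path <- file.path(dir, sprintf("%s_%s.tsv", round_id, safe))
    utils::write.table(groups[[gene]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths[gene] <- path
  }
  paths
}

is_mark <- function(x) tolower(trimws(x)) == "x"
is_blank <- function(x) !nzchar(trimws(x))

#' Ingest a filled curation sheet
#'
#' Parses the `x` marks of the decision columns (case-insensitive `x` is
#' the only truthy mark) and validates every row against the marking
#' protocol:
#' 1. any decision mark requires `checked` to be set;
#' 2. a row may not be marked both `correct` and `changed`;
#' 3. an `error_type` requires the row to be changed or uncorrectable, and
#'    must come from the controlled vocabulary;
#' 4. marks must be `x` or empty;
#' 5. curator-added rows (extra statements sharing a known uuid) must be
#'    marked changed, not correct.
#'
#' Violations are returned as structured findings (row number, rule id,
#' message); rows with findings are excluded from the returned valid rows.
#' An unknown or missing column is a hard error.
#'
#' @param path sheet TSV path (or a data frame already in sheet layout)
#' @param machine_rows optional data frame with columns `uuid` and `bel`
#'   describing the machine-origin rows of the generated sheet; enables the
#'   curator-added-row check (rule 5). A statement assembled into several
#'   edges legitimately contributes several machine rows sharing a uuid, so
#'   identity is the (uuid, bel) pair: a row with a known uuid but an
#'   unlisted statement is a curator addition.
#' @param extra_error_types additional permitted error-type codes
#' @return list with `rows` (data frame of valid rows, marks as logicals)
#'   and `findings` (data frame: row, rule, message)
#' @export
ingest_sheet <- function(path, machine_rows = NULL, extra_error_types = character()) {
  raw <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                      quote = "", na.strings = NULL)
  }
  if (!identical(sort(names(raw)), sort(SHEET_COLS))) {
    unknown <- setdiff(names(raw), SHEET_COLS)
    missing <- setdiff(SHEET_COLS, names(raw))
    stop(sprintf(
      "sheet schema mismatch%s%s",
      if (length(unknown)) sprintf("; unknown column(s): %s", paste(unknown, collapse = ", ")) else "",
      if (length(missing)) sprintf("; missing column(s): %s", paste(missing, collapse = ", ")) else ""
    ))
  }
  raw <- raw[, SHEET_COLS, drop = FALSE]
  for (col in SHEET_COLS) raw[[col]] <- as.character(raw[[col]])
  vocab <- c(error_types(), extra_error_types)
  findings <- empty_df(c("rule", "message"))
  findings$row <- integer(0)
  add_finding <- function(row, rule, message) {
    findings <<- rbind(findings, data.frame(
      rule = rule, message = message, row = row, stringsAsFactors = FALSE
    ))
  }

  n <- nrow(raw)
  valid <- rep(TRUE, n)
  known_uuids <- if (!is.null(machine_rows)) unique(machine_rows$uuid)
  known_pairs <- if (!is.null(machine_rows)) paste(machine_rows$uuid, machine_rows$bel)
  for (i in seq_len(n)) {
    r <- raw[i, ]
    marks <- c(checked = r$checked, correct = r$correct, changed = r$changed)
    bad_marks <- !vapply(marks, function(m) is_mark(m) || is_blank(m), logical(1))
    if (any(bad_marks)) {
      add_finding(i, "mark-syntax", sprintf(
        "column(s) %s must contain 'x' or be empty",
        paste(names(marks)[bad_marks], collapse = ", ")
      ))
      valid[i] <- FALSE
      next
    }
    checked <- is_mark(r$checked)
    correct <- is_mark(r$correct)
    changed <- is_mark(r$changed)
    has_error <- !is_blank(r$error_type)

    if (!checked && (correct || changed || has_error)) {
      add_finding(i, "rule1", "decision marks present but 'checked' is empty")
      valid[i] <- FALSE
    }
    if (correct && changed) {
      add_finding(i, "rule2", "row marked both correct and changed")
      valid[i] <- FALSE
    }
    if (has_error && correct) {
      add_finding(i, "rule3", "error_type annotated on a row marked correct")
      valid[i] <- FALSE
    }
    if (has_error && !r$error_type %in% vocab) {
      add_finding(i, "vocabulary", sprintf(
        "error_type '%s' not in the controlled vocabulary", r$error_type
      ))
      valid[i] <- FALSE
    }
    if (!is.null(machine_rows)) {
      if (!r$uuid %in% known_uuids) {
        add_finding(i, "provenance", sprintf(
          "row uuid '%s' does not share provenance with any known statement", r$uuid
        ))
        valid[i] <- FALSE
      } else if (!paste(r$uuid, r$bel) %in% known_pairs && valid[i]) {
        # curator-added row for an extra statement in the same evidence
        if (correct || !changed) {
          add_finding(i, "rule5",
            "curator-added row must be marked changed and not correct")
          valid[i] <- FALSE
        }
      }
    }
  }

  rows <- raw[valid, , drop = FALSE]
  rows$checked <- is_mark(rows$checked)
  rows$correct <- is_mark(rows$correct)
  rows$changed <- is_mark(rows$changed)
  rows$error_type[vapply(rows$error_type, is_blank, logical(1))] <- NA_character_
  rownames(rows) <- NULL
  findings <- findings[, c("row", "rule", "message"), drop = FALSE]
  rownames(findings) <- NULL
  list(rows = rows, findings = findings)
}

#' Classify validated curation rows
#'
#' Each validated row maps to exactly one class: `correct` (marked
#' correct), `changed` (marked changed, not correct), `uncorrectable`
#' (checked but neither mark — the statement could not be fixed), or
#' `unchecked` (not yet evaluated).
#'
#' @param rows validated rows from [ingest_sheet()]
#' @return character vector of classes, one per row
#' @export
classify_rows <- function(rows) {
  ifelse(rows$correct, "correct",
    ifelse(rows$changed, "changed",
      ifelse(rows$checked, "uncorrectable", "unchecked")
    )
  )
}

#' Write validation findings as JSON lines
#'
#' @param findings findings data frame from [ingest_sheet()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_findings <- function(findings, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(findings))) {
    writeLines(jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
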