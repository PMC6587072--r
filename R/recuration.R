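# Re-curation quality gate: required-annotation checking and the
# multi-curator Likert confidence workflow.

#' Likert confidence scale
#'
#' Ordered levels used to grade statement reliability during re-curation.
#' The literal strings (note `"Very High"` with a space) are stored in the
#' `Confidence` annotation for document fidelity; this vector defines
#' their ordinal order, lowest first.
#'
#' @return ordered character vector
#' @export
confidence_levels <- function() {
  c("None", "Low", "Medium", "High", "Very High")
}

confidence_rank <- function(x) match(x, confidence_levels())

edge_confidence <- function(kg, i) {
  ann <- kg$edges$annotations_list[[i]]
  if ("Confidence" %in% names(ann)) unname(ann[["Confidence"]]) else NA_character_
}

set_edge_annotation <- function(kg, i, name, value) {
  ann <- kg$edges$annotations_list[[i]]
  ann[name] <- value
  kg$edges$annotations_list[[i]] <- ann
  kg
}

#' Check that every statement carries required annotations
#'
#' One violation per edge missing any required annotation, carrying the
#' citation and rendered statement so the curator can locate it. With an
#' empty requirement list the result is always empty.
#'
#' @param kg a [bel_kg()]
#' @param required character vector of annotation names (e.g.
#'   `"Confidence"`)
#' @return data frame with columns `edge`, `missing`, `citation`,
#'   `statement`
#' @export
check_required_annotations <- function(kg, required = "Confidence") {
  out <- data.frame(
    edge = integer(0), missing = character(0), citation = character(0),
    statement = character(0), stringsAsFactors = FALSE
  )
  if (!length(required) || !nrow(kg$edges)) return(out)
  for (i in seq_len(nrow(kg$edges))) {
    ann <- kg$edges$annotations_list[[i]]
    miss <- setdiff(required, names(ann))
    for (m in miss) {
      out <- rbind(out, data.frame(
        edge = i, missing = m, citation = kg$edges$citation[i],
        statement = kg_statement_text(kg, i), stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Second-curator confidence decision
#'
#' Implements the Likert guideline for the first re-curation pass:
#' * `nonsense` — the evidence contains no reasonable biological
#'   knowledge: the edge and all statements sharing the same evidence are
#'   deleted (scope switchable to same-citation).
#' * `unclear` — the right BEL representation is not clear: set
#'   `Confidence = "Low"` for later discussion.
#' * `wrong_fixed` — the statement is wrong and was fixed: the statement is
#'   replaced and `Confidence = "Medium"` set.
#' * `assertable` — the statement can be asserted from the evidence: set
#'   `Confidence = "High"`.
#'
#' An edge already at `"Very High"` is left untouched with a warning.
#'
#' @param kg a [bel_kg()]
#' @param edge edge row index
#' @param assessment one of `"nonsense"`, `"unclear"`, `"wrong_fixed"`,
#'   `"assertable"`
#' @param correction for `wrong_fixed`, the corrected BEL statement line
#' @param delete_scope for `nonsense`, whether related statements share the
#'   same `"evidence"` (default) or the whole `"citation"`
#' @return list with `kg` (updated graph) and `action` (record of what was
#'   done: `action`, `edge`, `confidence`, `n_deleted`)
#' @export
second_curator_decision <- function(kg, edge,
                                    assessment = c("nonsense", "unclear",
                                                   "wrong_fixed", "assertable"),
                                    correction = NULL,
                                    delete_scope = c("evidence", "citation")) {
  assessment <- match.arg(assessment)
  delete_scope <- match.arg(delete_scope)
  stopifnot(edge >= 1, edge <= nrow(kg$edges))
  conf <- edge_confidence(kg, edge)
  if (identical(conf, "Very High")) {
    warning("edge already at 'Very High' confidence; decision ignored")
    return(list(kg = kg, action = list(action = "noop", edge = edge,
                                       confidence = conf, n_deleted = 0L)))
  }
  if (assessment == "nonsense") {
    if (delete_scope == "evidence") {
      doomed <- kg$edges$evidence == kg$edges$evidence[edge] &
        kg$edges$citation == kg$edges$citation[edge]
    } else {
      doomed <- kg$edges$citation == kg$edges$citation[edge]
    }
    kg$edges <- kg$edges[!doomed, , drop = FALSE]
    rownames(kg$edges) <- NULL
    return(list(kg = kg, action = list(action = "delete", edge = edge,
                                       confidence = "None",
                                       n_deleted = as.integer(sum(doomed)))))
  }
  if (assessment == "wrong_fixed") {
    if (is.null(correction)) stop("wrong_fixed requires a corrected statement")
    fixed <- parse_bel_statement(correction)
    kg <- kg_add_entity(kg, fixed$subject)
    skey <- attr(kg, "last_key")
    kg <- kg_add_entity(kg, fixed$object)
    okey <- attr(kg, "last_key")
    kg$edges$subject[edge] <- skey
    kg$edges$object[edge] <- okey
    kg$edges$relation[edge] <- fixed$relation
    kg$edges$causal[edge] <- relation_is_causal(fixed$relation)
    kg$edges$subject_activity[edge] <- fixed$subject_activity
    kg$edges$object_activity[edge] <- fixed$object_activity
    kg <- set_edge_annotation(kg, edge, "Confidence", "Medium")
    return(list(kg = kg, action = list(action = "fix", edge = edge,
                                       confidence = "Medium", n_deleted = 0L)))
  }
  new_conf <- if (assessment == "unclear") "Low" else "High"
  kg <- set_edge_annotation(kg, edge, "Confidence", new_conf)
  list(kg = kg, action = list(action = "annotate", edge = edge,
                              confidence = new_conf, n_deleted = 0L))
}

#' Third-curator (curation leader) review
#'
#' Only statements at `"Medium"` or `"High"` confidence are eligible. On
#' agreement the confidence is promoted to `"Very High"` — the only way
#' any statement can reach that level. On disagreement a fix action is
#' recorded and the confidence left unchanged pending re-review.
#'
#' @param kg a [bel_kg()]
#' @param edge edge row index
#' @param agree does the reviewer agree with the statement?
#' @return list with `kg` and `action` (`action`, `edge`, `confidence`)
#' @export
third_curator_review <- function(kg, edge, agree) {
  stopifnot(edge >= 1, edge <= nrow(kg$edges))
  conf <- edge_confidence(kg, edge)
  if (is.na(conf) || !conf %in% c("Medium", "High")) {
    stop(sprintf(
      "edge %d has confidence '%s'; only Medium/High statements are eligible for review",
      edge, conf %||% "<none>"
    ))
  }
  if (isTRUE(agree)) {
    kg <- set_edge_annotation(kg, edge, "Confidence", "Very High")
    return(list(kg = kg, action = list(action = "promote", edge = edge,
                                       confidence = "Very High")))
  }
  list(kg = kg, action = list(action = "fix_requested", edge = edge,
                              confidence = conf))
}

#' Apply an old-label to new-identifier mapping table
#'
#' Supports the namespace-update step of re-curation: terminologies drift
#' (label changes, merges, deprecations), and documents curated by label
#' need remapping. The table is user-supplied (2-column TSV: `old`,
#' `new`, both as `NAMESPACE:identifier` keys); no live lookups are
#' performed.
#'
#' @param kg a [bel_kg()]
#' @param mapping data frame with columns `old`, `new`, or a TSV path
#' @return the updated graph
#' @export
apply_label_mapping <- function(kg, mapping) {
  if (is.character(mapping)) {
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  stopifnot(all(c("old", "new") %in% names(mapping)))
  remap <- stats::setNames(mapping$new, mapping$old)
  new_nodes <- list()
  key_map <- character(0)
  for (key in names(kg$nodes)) {
    ent <- kg$nodes[[key]]
    ek <- sprintf("%s:%s", ent$namespace, ent$identifier)
    if (ent$grounded && ek %in% names(remap)) {
      parts <- strsplit(remap[[ek]], ":", fixed = TRUE)[[1]]
      ent$namespace <- parts[1]
      ent$identifier <- paste(parts[-1], collapse = ":")
      ent$label <- ent$identifier
    }
    new_key <- bel_term(ent)
    new_nodes[[new_key]] <- ent
    key_map[key] <- new_key
  }
  kg$nodes <- new_nodes
  if (nrow(kg$edges)) {
    kg$edges$subject <- unname(key_map[kg$edges$subject])
    kg$edges$object <- unname(key_map[kg$edges$object])
  }
  kg
}
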