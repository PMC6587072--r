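# Conversion of machine-extracted statements into candidate BEL edges.

#' Assembly policy
#'
#' @param namespace_priority ordered namespace prefixes; when an entity
#'   carries several candidate groundings the earliest-listed namespace
#'   wins.
#' @param directness_default `"indirect"` (plain increases/decreases — the
#'   safe default, since direct physical contact is hard to detect
#'   automatically) or `"direct"` (directlyIncreases family).
#' @param allow_activity_on_processes when `FALSE` (default), an `act()`
#'   wrapper is never emitted around biological-process or pathology
#'   objects — activity is reserved for proteins and other physical
#'   entities — and the downgrade is logged.
#' @return a list of class `assembly_policy`
#' @export
assembly_policy <- function(namespace_priority = c(
                              "HGNC", "FPLX", "UP", "CHEBI", "GO", "MESH",
                              "DOID", "HP"
                            ),
                            directness_default = c("indirect", "direct"),
                            allow_activity_on_processes = FALSE) {
  stopifnot(length(namespace_priority) >= 1)
  directness_default <- match.arg(directness_default)
  structure(
    list(
      namespace_priority = toupper(namespace_priority),
      directness_default = directness_default,
      allow_activity_on_processes = allow_activity_on_processes
    ),
    class = "assembly_policy"
  )
}

#' Read an assembly policy from YAML
#' @param path YAML file with any of the policy fields
#' @return an [assembly_policy()]
#' @export
read_assembly_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(assembly_policy, cfg)
}

entity_class_for_candidate <- function(ns) {
  switch(toupper(ns),
    HGNC = "protein", UP = "protein", FPLX = "family",
    CHEBI = "abundance", MESH = "abundance",
    GO = "biological_process", DOID = "pathology", HP = "pathology",
    "protein"
  )
}

#' Ground an entity mention against a namespace priority
#'
#' Selects the candidate grounding whose namespace appears earliest in the
#' policy's priority list (ties broken by candidate order); with no usable
#' candidate the entity is returned ungrounded and flagged. The entity
#' class is inferred from the winning namespace (HGNC/UP to protein, FPLX
#' to family, CHEBI/MESH to abundance, GO to process, DOID/HP to
#' pathology).
#'
#' @param grounding a list with `label` and `candidates` (each a list with
#'   `namespace` and `identifier`), as parsed from the corpus JSON
#' @param policy an [assembly_policy()]
#' @return a [bel_entity()]
#' @export
ground_candidates <- function(grounding, policy = assembly_policy()) {
  label <- grounding$label %||% "unknown"
  cands <- grounding$candidates
  if (is.null(cands) || !length(cands)) {
    return(bel_entity("protein", label = label))
  }
  idx <- vapply(cands, function(c) {
    m <- match(toupper(c$namespace), policy$namespace_priority)
    if (is.na(m)) length(policy$namespace_priority) + 1L else m
  }, integer(1))
  best <- cands[[which.min(idx)]]
  bel_entity(
    entity_class_for_candidate(best$namespace),
    namespace = best$namespace, identifier = best$identifier, label = label
  )
}

assembled_cols <- c(
  "uuid", "gene", "citation", "evidence", "bel", "relation",
  "statement_type", "belief"
)

wrap_activity <- function(entity, policy, log_fun) {
  if (entity$entity_class %in% c("biological_process", "pathology") &&
      !policy$allow_activity_on_processes) {
    log_fun(sprintf(
      "activity wrapper suppressed on %s term %s",
      entity$entity_class, bel_term(entity)
    ))
    return(FALSE)
  }
  TRUE
}

#' Assemble one extracted statement into candidate BEL edges
#'
#' Assembly semantics:
#' * activation — subject increases `act(object)`; inhibition — decreases.
#' * phosphorylation / other modification — subject increases the modified
#'   protein node, plus a `hasVariant` edge from the reference protein to
#'   the modified node.
#' * complex formation over members M1..Mn — a composed complex node with a
#'   membership edge to each member and pairwise bidirectional association
#'   statements: n + n(n-1) edges in total.
#' * regulate_amount — a regulates edge onto the unmodified target.
#'
#' The directness default selects the plain vs `directly` relation family.
#' An `act()` wrapper is never emitted around process/pathology objects
#' under the default policy (logged as a fix). Negated statements and
#' statements with an ungroundable required entity produce no edges, only
#' a structured skip record. Every emitted edge carries the source
#' statement's uuid, evidence and citation.
#'
#' @param statements a [bel_corpus] subset (one or more rows)
#' @param policy an [assembly_policy()]
#' @return a list with `edges` (data frame: uuid, gene, citation, evidence,
#'   bel, relation, statement_type, belief), `skips` and `fixes` (data
#'   frames of structured log records)
#' @export
assemble_statements <- function(statements, policy = assembly_policy()) {
  skips <- empty_df(c("uuid", "reason"))
  fixes <- empty_df(c("uuid", "message"))
  rows <- list()

  inc <- if (policy$directness_default == "direct") "directly_increases" else "increases"
  dec <- if (policy$directness_default == "direct") "directly_decreases" else "decreases"

  for (i in seq_len(nrow(statements))) {
    st <- statements[i, ]
    uuid <- st$uuid
    gene <- st$gene %||% NA_character_
    add_skip <- function(reason) {
      skips <<- rbind(skips, data.frame(uuid = uuid, reason = reason,
                                        stringsAsFactors = FALSE))
    }
    add_fix <- function(message) {
      fixes <<- rbind(fixes, data.frame(uuid = uuid, message = message,
                                        stringsAsFactors = FALSE))
    }
    emit <- function(subject, relation, object,
                     subject_activity = FALSE, object_activity = FALSE) {
      subj_txt <- bel_term(subject)
      obj_txt <- bel_term(object)
      if (subject_activity) subj_txt <- sprintf("act(%s)", subj_txt)
      if (object_activity) obj_txt <- sprintf("act(%s)", obj_txt)
      bel <- sprintf("%s %s %s", subj_txt, unname(REL_TO_KEYWORD[relation]), obj_txt)
      rows[[length(rows) + 1L]] <<- data.frame(
        uuid = uuid, gene = gene, citation = st$citation,
        evidence = flatten_ws(st$evidence), bel = bel, relation = relation,
        statement_type = st$statement_type, belief = st$belief,
        stringsAsFactors = FALSE
      )
    }

    if (isTRUE(st$negated)) {
      add_skip("negated statement; negative assertions are not assembled")
      next
    }

    type <- st$statement_type
    if (type == "complex_formation") {
      members <- lapply(st$members_cand[[1]], ground_candidates, policy = policy)
      grounded <- vapply(members, function(e) e$grounded, logical(1))
      if (length(members) < 2 || !all(grounded)) {
        add_skip("complex with fewer than two groundable members")
        next
      }
      cplx <- bel_entity("complex", members = members)
      for (m in members) emit(cplx, "complex_membership", m)
      n <- length(members)
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          if (a != b) emit(members[[a]], "association", members[[b]])
        }
      }
      next
    }

    subj <- ground_candidates(st$subject_cand[[1]], policy)
    obj <- ground_candidates(st$object_cand[[1]], policy)
    if (!subj$grounded || !obj$grounded) {
      add_skip("ungroundable subject or object")
      next
    }

    if (type %in% c("activation", "inhibition")) {
      act_ok <- wrap_activity(obj, policy, add_fix)
      emit(subj, if (type == "activation") inc else dec, obj,
           object_activity = act_ok)
    } else if (type %in% c("phosphorylation", "other_modification")) {
      if (!obj$entity_class %in% c("protein", "family")) {
        add_skip("modification target is not a protein")
        next
      }
      mod <- if (type == "phosphorylation") {
        residue <- if (nzchar(st$mod_residue %||% "")) st$mod_residue else NULL
        position <- if (nzchar(st$mod_position %||% "")) st$mod_position else NULL
        bel_modification("phosphorylation", residue = residue, position = position)
      } else {
        bel_modification("other_ptm")
      }
      modified <- bel_entity(
        "protein", namespace = obj$namespace, identifier = obj$identifier,
        label = obj$label, variants = list(mod)
      )
      reference <- bel_entity(
        "protein", namespace = obj$namespace, identifier = obj$identifier,
        label = obj$label
      )
      emit(subj, inc, modified)
      emit(reference, "has_variant", modified)
    } else if (type == "regulate_amount") {
      emit(subj, "regulates", obj)
    } else {
      emit(subj, "association", obj)
    }
  }

  edges <- if (length(rows)) do.call(rbind, rows) else empty_df(assembled_cols)
  edges$belief <- as.numeric(edges$belief)
  rownames(edges) <- NULL
  list(edges = edges, skips = skips, fixes = fixes)
}
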