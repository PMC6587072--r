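# Knowledge-graph container: a directed multigraph of grounded entities
# with typed, annotated, evidence-bearing edges.

#' Relation types of the BEL subset
#' @export
BEL_RELATIONS <- c(
  "increases", "directly_increases", "decreases", "directly_decreases",
  "regulates", "complex_membership", "has_variant", "association",
  "correlation", "ontological"
)

CAUSAL_RELATIONS <- c(
  "increases", "directly_increases", "decreases", "directly_decreases",
  "regulates"
)

REL_TO_KEYWORD <- c(
  increases = "increases", directly_increases = "directlyIncreases",
  decreases = "decreases", directly_decreases = "directlyDecreases",
  regulates = "regulates", complex_membership = "hasComponent",
  has_variant = "hasVariant", association = "association",
  correlation = "correlation", ontological = "isA"
)

KEYWORD_TO_REL <- c(
  increases = "increases", "->" = "increases",
  directlyIncreases = "directly_increases", "=>" = "directly_increases",
  decreases = "decreases", "-|" = "decreases",
  directlyDecreases = "directly_decreases", "=|" = "directly_decreases",
  regulates = "regulates", reg = "regulates",
  hasComponent = "complex_membership", hasVariant = "has_variant",
  association = "association", "--" = "association",
  correlation = "correlation", positiveCorrelation = "correlation",
  negativeCorrelation = "correlation",
  isA = "ontological", partOf = "ontological"
)

#' Is a relation causal?
#'
#' Causality is a pure function of the relation type: the four
#' increase/decrease forms and `regulates` are causal; membership, variant,
#' associative, correlative and ontological relations are not.
#'
#' @param relation character vector of relation types
#' @return logical vector
#' @export
relation_is_causal <- function(relation) {
  relation %in% CAUSAL_RELATIONS
}

edge_cols <- c(
  "uuid", "subject", "object", "relation", "causal",
  "subject_activity", "object_activity", "evidence", "citation",
  "annotations_list"
)

#' Create an empty knowledge graph
#'
#' @param name document name
#' @param version document version
#' @param namespaces named character vector mapping namespace prefixes to
#'   resource URLs (plain prefixes are given a placeholder URL).
#' @return an object of class `bel_kg`
#' @export
bel_kg <- function(name = "untitled", version = "0.0.0", namespaces = character()) {
  if (length(namespaces) && is.null(names(namespaces))) {
    urls <- sprintf("https://example.org/namespaces/%s.belns", tolower(namespaces))
    namespaces <- stats::setNames(urls, namespaces)
  }
  structure(
    list(
      nodes = list(),
      edges = empty_df(edge_cols),
      metadata = list(name = name, version = version, namespaces = namespaces),
      errors = empty_df(c("line", "column", "message")),
      warnings = empty_df(c("line", "message"))
    ),
    class = "bel_kg"
  )
}

fix_edge_types <- function(edges) {
  edges$causal <- as.logical(edges$causal)
  edges$subject_activity <- as.logical(edges$subject_activity)
  edges$object_activity <- as.logical(edges$object_activity)
  edges
}

#' Add an entity node to a knowledge graph
#'
#' The node key is the canonical BEL term string; re-adding an existing key
#' is a no-op.
#'
#' @param kg a [bel_kg()]
#' @param entity a [bel_entity()]
#' @return the updated graph (invisibly carries the key as an attribute)
#' @export
kg_add_entity <- function(kg, entity) {
  stopifnot(inherits(kg, "bel_kg"), inherits(entity, "bel_entity"))
  key <- bel_term(entity)
  if (is.null(kg$nodes[[key]])) kg$nodes[[key]] <- entity
  if (entity$grounded && !entity$namespace %in% names(kg$metadata$namespaces)) {
    url <- sprintf("https://example.org/namespaces/%s.belns", tolower(entity$namespace))
    kg$metadata$namespaces[entity$namespace] <- url
  }
  attr(kg, "last_key") <- key
  kg
}

#' Add an edge (statement) to a knowledge graph
#'
#' Endpoints are added as nodes if absent. Parallel edges between the same
#' endpoints are permitted only when (evidence, citation, relation) differ;
#' an exact duplicate is merged silently. Statement identity (`uuid`) is a
#' fingerprint of (subject, relation, object, citation, evidence) unless an
#' explicit identifier is supplied.
#'
#' @param kg a [bel_kg()]
#' @param subject,object [bel_entity()] endpoints
#' @param relation one of [BEL_RELATIONS]
#' @param evidence supporting sentence
#' @param citation citation identifier (e.g. a PubMed id)
#' @param annotations named character vector of annotation values (may
#'   include `"Confidence"`)
#' @param uuid optional explicit statement identifier
#' @param subject_activity,object_activity whether the endpoint appears
#'   inside an `act()` wrapper in the statement
#' @return the updated graph
#' @export
kg_add_edge <- function(kg, subject, object, relation,
                        evidence = "", citation = "",
                        annotations = character(),
                        uuid = NULL,
                        subject_activity = FALSE, object_activity = FALSE) {
  stopifnot(inherits(kg, "bel_kg"))
  relation <- match.arg(relation, BEL_RELATIONS)
  kg <- kg_add_entity(kg, subject)
  skey <- attr(kg, "last_key")
  kg <- kg_add_entity(kg, object)
  okey <- attr(kg, "last_key")
  evidence <- flatten_ws(evidence %||% "")
  citation <- as.character(citation %||% "")
  dup <- kg$edges$subject == skey & kg$edges$object == okey &
    kg$edges$relation == relation & kg$edges$citation == citation &
    kg$edges$evidence == evidence
  if (any(dup)) return(kg)
  if (is.null(uuid)) {
    uuid <- str_fingerprint(paste(skey, relation, okey, citation, evidence, sep = "\r"))
  }
  ann <- as.character(annotations)
  names(ann) <- names(annotations)
  row <- data.frame(
    uuid = uuid, subject = skey, object = okey, relation = relation,
    causal = relation_is_causal(relation),
    subject_activity = subject_activity, object_activity = object_activity,
    evidence = evidence, citation = citation,
    annotations_list = I(list(ann)),
    stringsAsFactors = FALSE
  )
  kg$edges <- fix_edge_types(rbind(kg$edges, row))
  kg
}

#' Number of nodes / edges
#' @param kg a [bel_kg()]
#' @return integer count
#' @export
kg_n_nodes <- function(kg) length(kg$nodes)

#' @rdname kg_n_nodes
#' @export
kg_n_edges <- function(kg) nrow(kg$edges)

#' @export
print.bel_kg <- function(x, ...) {
  cat(sprintf(
    "<bel_kg> %s v%s: %d nodes, %d edges (%d causal)\n",
    x$metadata$name, x$metadata$version, kg_n_nodes(x), kg_n_edges(x),
    sum(x$edges$causal)
  ))
  if (nrow(x$errors)) cat(sprintf("  %d parse error(s)\n", nrow(x$errors)))
  invisible(x)
}

#' Render one edge as a BEL statement line
#'
#' @param kg a [bel_kg()]
#' @param i edge row index
#' @return a single statement string
#' @export
kg_statement_text <- function(kg, i) {
  e <- kg$edges[i, ]
  subj <- if (e$subject_activity) sprintf("act(%s)", e$subject) else e$subject
  obj <- if (e$object_activity) sprintf("act(%s)", e$object) else e$object
  sprintf("%s %s %s", subj, unname(REL_TO_KEYWORD[e$relation]), obj)
}

#' Convert a knowledge graph to an igraph multigraph
#'
#' Directed; one igraph edge per statement (evidence), so degree counts
#' parallel evidences and self-loops contribute 2 to total degree.
#'
#' @param kg a [bel_kg()]
#' @return an `igraph` object with node names equal to the graph's keys
#' @export
kg_igraph <- function(kg) {
  igraph::graph_from_data_frame(
    kg$edges[, c("subject", "object")],
    directed = TRUE,
    vertices = data.frame(name = names(kg$nodes), stringsAsFactors = FALSE)
  )
}

#' Canonical triple of an edge
#'
#' Collapses the edge to gene level: endpoints are reduced with
#' [canonical_key()] (variants stripped, rna/protein mapped to the cognate
#' gene key) and the relation is reduced to a coarse class —
#' increases/directlyIncreases to `up`, decreases forms to `down`,
#' `regulates` kept, membership and association/binding classes with sorted
#' endpoints (they are direction-free), everything else `other`. Two edges
#' are curation-equivalent iff their triples are equal and comparable.
#'
#' @param subject,object [bel_entity()] endpoints (or, in the two-argument
#'   form, `kg` and an edge index `i`)
#' @param relation relation type
#' @return a list with `subject_key`, `relation_class`, `object_key`,
#'   `comparable` (FALSE when an endpoint is ungroundable) and `key`, a
#'   single comparison string
#' @export
canonical_triple <- function(subject, object, relation) {
  skey <- canonical_key(subject)
  okey <- canonical_key(object)
  rel_class <- switch(relation,
    increases = , directly_increases = "up",
    decreases = , directly_decreases = "down",
    regulates = "regulates",
    association = , correlation = "binds",
    complex_membership = "membership",
    "other"
  )
  comparable <- !is.na(skey) && !is.na(okey)
  if (comparable && rel_class %in% c("binds", "membership")) {
    ends <- sort(c(skey, okey))
    skey <- ends[1]
    okey <- ends[2]
  }
  key <- if (comparable) paste(skey, rel_class, okey, sep = " | ") else NA_character_
  list(
    subject_key = skey, relation_class = rel_class, object_key = okey,
    comparable = comparable, key = key
  )
}

#' Canonical triple keys for every edge of a graph
#'
#' @param kg a [bel_kg()]
#' @return character vector, `NA` for non-comparable edges
#' @export
kg_triple_keys <- function(kg) {
  if (!nrow(kg$edges)) return(character(0))
  vapply(seq_len(nrow(kg$edges)), function(i) {
    e <- kg$edges[i, ]
    tr <- canonical_triple(kg$nodes[[e$subject]], kg$nodes[[e$object]], e$relation)
    if (tr$comparable) tr$key else NA_character_
  }, character(1))
}
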