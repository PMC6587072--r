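# Entity and modification model for the BEL subset.

#' Entity classes recognised by the knowledge-graph model
#'
#' Central-dogma classes (gene, rna, microrna, protein) can carry variants
#' and collapse to a common gene-level key; the remaining classes are
#' physical or process entities that the enrichment preprocessing removes.
#'
#' @export
BEL_ENTITY_CLASSES <- c(
  "gene", "rna", "microrna", "protein", "abundance", "complex",
  "family", "biological_process", "pathology", "reaction"
)

# BEL function keyword for each entity class (families render as p() under
# FamPlex-style namespaces, as in real documents).
CLASS_TO_FUNC <- c(
  gene = "g", rna = "r", microrna = "m", protein = "p", abundance = "a",
  complex = "complex", family = "p", biological_process = "bp",
  pathology = "path", reaction = "rxn"
)

FUNC_TO_CLASS <- c(
  g = "gene", r = "rna", m = "microrna", p = "protein", a = "abundance",
  complex = "complex", bp = "biological_process", path = "pathology",
  rxn = "reaction"
)

MOD_TYPES <- c("phosphorylation", "ubiquitination", "other_ptm", "sequence_variant")

# BEL pmod() codes for the modification types we model.
MOD_CODE <- c(phosphorylation = "Ph", ubiquitination = "Ub")

#' Post-translational modification or sequence variant
#'
#' @param mod_type one of `"phosphorylation"`, `"ubiquitination"`,
#'   `"other_ptm"`, `"sequence_variant"`.
#' @param residue optional amino-acid residue (e.g. `"Ser"`); required when
#'   `position` is given.
#' @param position optional positive integer position on the protein.
#' @param code BEL modification code; defaults to `Ph`/`Ub` for the named
#'   types and `Mod` for other PTMs.
#' @return an object of class `bel_modification`
#' @export
bel_modification <- function(mod_type = MOD_TYPES, residue = NULL,
                             position = NULL, code = NULL) {
  mod_type <- match.arg(mod_type)
  if (!is.null(position)) {
    if (is.null(residue)) stop("modification position requires a residue")
    position <- as.integer(position)
    if (is.na(position) || position < 1L) stop("position must be a positive integer")
  }
  if (is.null(code)) {
    code <- if (mod_type %in% names(MOD_CODE)) unname(MOD_CODE[mod_type]) else "Mod"
  }
  structure(
    list(mod_type = mod_type, residue = residue, position = position, code = code),
    class = "bel_modification"
  )
}

render_modification <- function(m) {
  if (m$mod_type == "sequence_variant") {
    return(sprintf('var("%s")', bel_escape(m$residue %||% "?")))
  }
  parts <- m$code
  if (!is.null(m$residue)) parts <- c(parts, m$residue)
  if (!is.null(m$position)) parts <- c(parts, m$position)
  sprintf("pmod(%s)", paste(parts, collapse = ", "))
}

#' Grounded biological entity
#'
#' An entity is grounded when both `namespace` and `identifier` are
#' non-empty; ungrounded entities are carried with an explicit flag so that
#' downstream steps can route them to a curator instead of silently
#' dropping them. Variants (see [bel_modification()]) are only permitted on
#' the gene/rna/protein classes.
#'
#' @param entity_class one of [BEL_ENTITY_CLASSES].
#' @param namespace terminology prefix (e.g. `"HGNC"`, `"CHEBI"`, `"GO"`).
#' @param identifier identifier or preferred label within the namespace.
#' @param label human-readable label; defaults to the identifier.
#' @param variants list of [bel_modification()] objects.
#' @param members for composed complexes, an ordered list of member entities.
#' @return an object of class `bel_entity`
#' @export
bel_entity <- function(entity_class, namespace = NA_character_,
                       identifier = NA_character_, label = NULL,
                       variants = list(), members = list()) {
  entity_class <- match.arg(entity_class, BEL_ENTITY_CLASSES)
  namespace <- as.character(namespace)
  identifier <- as.character(identifier)
  grounded <- !is.na(namespace) && nzchar(namespace) &&
    !is.na(identifier) && nzchar(identifier)
  if (length(variants) && !entity_class %in% c("gene", "rna", "protein")) {
    stop("variants only permitted on gene/rna/protein entities")
  }
  if (length(variants) && !all(vapply(variants, inherits, logical(1), "bel_modification"))) {
    stop("variants must be bel_modification objects")
  }
  if (length(members) && entity_class != "complex") {
    stop("members only permitted on complex entities")
  }
  structure(
    list(
      entity_class = entity_class,
      namespace = namespace,
      identifier = identifier,
      label = label %||% identifier,
      variants = variants,
      members = members,
      grounded = grounded
    ),
    class = "bel_entity"
  )
}

#' @export
print.bel_entity <- function(x, ...) {
  cat("<bel_entity> ", bel_term(x), "\n", sep = "")
  invisible(x)
}

quote_if_needed <- function(x) {
  if (grepl("^[A-Za-z0-9_.-]+$", x)) x else sprintf('"%s"', bel_escape(x))
}

#' Render an entity as a BEL term string
#'
#' The rendered term doubles as the entity's node key in the knowledge
#' graph, so rendering is canonical: fixed argument order, variants in the
#' order given, composed complexes listing members in order.
#'
#' @param entity a [bel_entity()]
#' @return a single BEL term string, e.g. `p(HGNC:MAPT, pmod(Ph, Ser, 396))`
#' @export
bel_term <- function(entity) {
  stopifnot(inherits(entity, "bel_entity"))
  fn <- unname(CLASS_TO_FUNC[entity$entity_class])
  if (entity$entity_class == "complex" && length(entity$members)) {
    inner <- vapply(entity$members, bel_term, character(1))
    return(sprintf("complex(%s)", paste(inner, collapse = ", ")))
  }
  ns_arg <- if (entity$grounded) {
    sprintf("%s:%s", entity$namespace, quote_if_needed(entity$identifier))
  } else {
    # explicit ungrounded marker keeps the term parseable and flagged
    sprintf('TEXT:%s', quote_if_needed(entity$label %||% "unknown"))
  }
  args <- ns_arg
  if (length(entity$variants)) {
    args <- c(args, vapply(entity$variants, render_modification, character(1)))
  }
  sprintf("%s(%s)", fn, paste(args, collapse = ", "))
}

#' Canonical gene-level key for an entity
#'
#' Maps RNA, microRNA, protein and variant forms of the same gene to a
#' single `NAMESPACE:identifier` key (variants stripped), so that
#' deduplication and collapsing treat all products of a gene as one node.
#' Protein families keep their family key; other classes are prefixed with
#' their class so that, e.g., a GO process and an HGNC gene can never
#' collide. Ungrounded entities return `NA`.
#'
#' @param entity a [bel_entity()]
#' @return a single character key, or `NA_character_` if ungrounded
#' @export
canonical_key <- function(entity) {
  stopifnot(inherits(entity, "bel_entity"))
  if (entity$entity_class == "complex" && length(entity$members)) {
    keys <- vapply(entity$members, canonical_key, character(1))
    if (anyNA(keys)) return(NA_character_)
    return(sprintf("complex(%s)", paste(sort(keys), collapse = "|")))
  }
  if (!entity$grounded) return(NA_character_)
  base <- sprintf("%s:%s", toupper(entity$namespace), entity$identifier)
  if (entity$entity_class %in% c("gene", "rna", "microrna", "protein", "family")) {
    base
  } else {
    sprintf("%s:%s", entity$entity_class, base)
  }
}

# TRUE for keys that survive enrichment preprocessing (gene-collapsible).
is_gene_level <- function(entity) {
  entity$entity_class %in% c("gene", "rna", "microrna", "protein", "family")
}
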