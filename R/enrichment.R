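# Curation prioritisation: gene-level collapsing, causal filtering and
# ranking by information density (in-degree + out-degree).

#' Preprocessing configuration
#'
#' Controls the reduction of a full knowledge graph to a causal, gene-level
#' graph before ranking. Defaults follow the standard enrichment recipe:
#' collapse RNA/microRNA/protein/variant nodes onto their gene, drop
#' non-causal relations (associative, correlative, ontological, membership,
#' variant) and remove chemical abundances, reactions, pathologies and
#' biological processes. The exclusion list can be adapted for other
#' downstream applications (e.g. keep abundances for metabolic questions)
#' but may never exclude genes.
#'
#' @param collapse_central_dogma collapse gene products onto the gene key
#' @param remove_noncausal drop non-causal edges
#' @param excluded_entity_classes entity classes removed with their
#'   incident edges
#' @return a list of class `preprocess_config`
#' @export
preprocess_config <- function(collapse_central_dogma = TRUE,
                              remove_noncausal = TRUE,
                              excluded_entity_classes = c(
                                "abundance", "reaction", "pathology",
                                "biological_process"
                              )) {
  excluded_entity_classes <- match.arg(
    excluded_entity_classes, BEL_ENTITY_CLASSES, several.ok = TRUE
  )
  if ("gene" %in% excluded_entity_classes) {
    stop("excluded entity classes may never include 'gene'")
  }
  structure(
    list(
      collapse_central_dogma = collapse_central_dogma,
      remove_noncausal = remove_noncausal,
      excluded_entity_classes = excluded_entity_classes
    ),
    class = "preprocess_config"
  )
}

#' Reduce a knowledge graph to its causal, gene-level core
#'
#' Applies, in order: removal of excluded entity classes (and their
#' incident edges), removal of non-causal edges, and central-dogma
#' collapsing — every node corresponding to a product or variant of gene G
#' is rewired onto G's canonical key. Composed complexes and any node that
#' cannot be reduced to a gene-level key are removed as well, so the result
#' contains only gene-level nodes and causal edges among them. Duplicate
#' rewired edges with identical (canonical triple, citation, evidence) are
#' merged. Self-loops arising from collapsing (e.g. autoregulation) are
#' kept. The operation is idempotent.
#'
#' @param kg a [bel_kg()]
#' @param config a [preprocess_config()]
#' @return a gene-level [bel_kg()]
#' @export
preprocess <- function(kg, config = preprocess_config()) {
  stopifnot(inherits(kg, "bel_kg"))
  out <- bel_kg(
    name = kg$metadata$name, version = kg$metadata$version,
    namespaces = kg$metadata$namespaces
  )
  if (!nrow(kg$edges)) {
    # carry over surviving isolated nodes
    for (key in names(kg$nodes)) {
      ent <- kg$nodes[[key]]
      if (ent$entity_class %in% config$excluded_entity_classes) next
      ck <- canonical_key(ent)
      if (is.na(ck) || !is_gene_level(ent)) next
      out <- kg_add_entity(out, gene_entity_for_key(ck))
    }
    return(out)
  }

  seen <- character(0)
  for (i in seq_len(nrow(kg$edges))) {
    e <- kg$edges[i, ]
    s_ent <- kg$nodes[[e$subject]]
    o_ent <- kg$nodes[[e$object]]
    if (s_ent$entity_class %in% config$excluded_entity_classes) next
    if (o_ent$entity_class %in% config$excluded_entity_classes) next
    if (config$remove_noncausal && !e$causal) next
    if (!is_gene_level(s_ent) || !is_gene_level(o_ent)) next
    skey <- if (config$collapse_central_dogma) canonical_key(s_ent) else e$subject
    okey <- if (config$collapse_central_dogma) canonical_key(o_ent) else e$object
    if (is.na(skey) || is.na(okey)) next
    tr <- canonical_triple(s_ent, o_ent, e$relation)
    dedup_key <- paste(tr$key, e$citation, e$evidence, sep = "\r")
    if (dedup_key %in% seen) next
    seen <- c(seen, dedup_key)
    out <- kg_add_edge(
      out, gene_entity_for_key(skey), gene_entity_for_key(okey), e$relation,
      evidence = e$evidence, citation = e$citation,
      annotations = e$annotations_list[[1]], uuid = e$uuid
    )
  }
  # isolated survivors (gene-level nodes whose every edge was removed)
  for (key in names(kg$nodes)) {
    ent <- kg$nodes[[key]]
    if (ent$entity_class %in% config$excluded_entity_classes) next
    if (!is_gene_level(ent)) next
    ck <- canonical_key(ent)
    if (is.na(ck)) next
    out <- kg_add_entity(out, gene_entity_for_key(ck))
  }
  out
}

# A gene-level entity whose term string *is* the canonical key, so that
# preprocess(preprocess(G)) == preprocess(G).
gene_entity_for_key <- function(key) {
  parts <- regmatches(key, regexec("^([^:]+):(.*)$", key))[[1]]
  ent <- bel_entity("gene", namespace = parts[2], identifier = parts[3])
  ent
}

# In the collapsed graph node keys are rendered terms g(NS:ID); map between
# canonical keys and node keys.
node_key_for_gene <- function(kg, gene_key) {
  want <- bel_term(gene_entity_for_key(gene_key))
  if (!is.null(kg$nodes[[want]])) return(want)
  if (!is.null(kg$nodes[[gene_key]])) return(gene_key)
  NA_character_
}

gene_key_for_node <- function(kg, node_key) {
  canonical_key(kg$nodes[[node_key]])
}

#' Information density of a gene
#'
#' The sum of in-degree and out-degree of the gene's node in the
#' pre-processed (causal, gene-level) graph, counting parallel edges — each
#' independent evidence contributes one unit of causal information, and a
#' self-loop contributes two. Isolated nodes score 0: genes for which the
#' graph holds no causal information, hence the highest curation priority.
#'
#' @param kg a pre-processed [bel_kg()] (see [preprocess()])
#' @param gene_key canonical gene key, e.g. `"HGNC:MAPT"`
#' @param count_evidences when `FALSE`, parallel evidences for the same
#'   canonical triple are counted once
#' @return non-negative integer
#' @export
information_density <- function(kg, gene_key, count_evidences = TRUE) {
  node <- node_key_for_gene(kg, gene_key)
  if (is.na(node)) stop(sprintf("gene '%s' not found in graph", gene_key))
  edges <- kg$edges
  if (!count_evidences && nrow(edges)) {
    edges <- edges[!duplicated(kg_triple_keys(kg)), , drop = FALSE]
  }
  if (!nrow(edges)) return(0L)
  g <- igraph::graph_from_data_frame(
    edges[, c("subject", "object")], directed = TRUE,
    vertices = data.frame(name = names(kg$nodes))
  )
  as.integer(igraph::degree(g, v = node, mode = "all", loops = TRUE))
}

#' Rank genes by ascending information density
#'
#' Lowest density first: the genes the graph knows least about are the
#' highest curation priority. Ties are broken lexicographically by
#' (namespace, identifier), so the ranking is a deterministic total order,
#' invariant under permutation of the input graph.
#'
#' @param kg a pre-processed [bel_kg()]
#' @param exclude gene keys to omit (e.g. genes already curated in earlier
#'   rounds, so iterative rounds surface new low-density genes)
#' @param count_evidences see [information_density()]
#' @return data frame with columns `gene_key`, `information_density`,
#'   `rank` (1..n)
#' @export
rank_genes <- function(kg, exclude = character(), count_evidences = TRUE) {
  keys <- vapply(names(kg$nodes), gene_key_for_node, character(1), kg = kg)
  keys <- unname(keys[!is.na(keys)])
  keys <- sort(unique(setdiff(keys, exclude)), method = "radix")
  dens <- vapply(keys, information_density, integer(1),
                 kg = kg, count_evidences = count_evidences)
  ord <- order(dens, keys, method = "radix")
  data.frame(
    gene_key = keys[ord],
    information_density = as.integer(dens[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}

#' Select the genes for one curation round
#'
#' @param ranked output of [rank_genes()]
#' @param k number of genes per round (default 30)
#' @return character vector of at most `k` gene keys, highest priority first
#' @export
select_round <- function(ranked, k = 30L) {
  stopifnot(k >= 1)
  utils::head(ranked$gene_key, k)
}

#' Export a ranking as TSV
#'
#' @param ranked output of [rank_genes()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_ranking <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
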