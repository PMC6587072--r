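# Shared fixtures and independent oracles. Oracles are deliberately naive
# (row scans, pairwise comparisons) so they stay independent of the code
# paths they check.

# Small hand-built graph: 3 proteins, one process, a mix of relations.
toy_kg <- function() {
  kg <- bel_kg(name = "toy")
  A <- bel_entity("protein", "HGNC", "AAA1")
  B <- bel_entity("biological_process", "GO", "0006915")
  C <- bel_entity("protein", "HGNC", "CCC3")
  Ar <- bel_entity("rna", "HGNC", "AAA1")
  Avar <- bel_entity("protein", "HGNC", "AAA1",
                     variants = list(bel_modification("phosphorylation")))
  kg <- kg_add_edge(kg, A, B, "increases", evidence = "e1", citation = "1")
  kg <- kg_add_edge(kg, Ar, C, "association", evidence = "e2", citation = "1")
  kg <- kg_add_edge(kg, Avar, C, "decreases", evidence = "e3", citation = "2")
  kg
}

# Brute-force incident-edge count: scans the raw edge table.
oracle_density <- function(kg, node_key) {
  sum(kg$edges$subject == node_key) + sum(kg$edges$object == node_key)
}

# Degree of a canonical gene key in a collapsed graph, by scanning.
oracle_density_gene <- function(kg, gene_key) {
  node <- NA_character_
  for (k in names(kg$nodes)) {
    if (identical(canonical_key(kg$nodes[[k]]), gene_key)) { node <- k; break }
  }
  oracle_density(kg, node)
}

# Pairwise curation-equivalence comparator working directly on entity
# fields, no canonical_triple involved: used to check that triple equality
# induces the same partition.
oracle_edges_equivalent <- function(kg, i, j) {
  gene_key_naive <- function(ent) {
    if (!ent$grounded) return(NA_character_)
    if (ent$entity_class %in% c("gene", "rna", "microrna", "protein", "family")) {
      paste0(toupper(ent$namespace), ":", ent$identifier)
    } else {
      paste(ent$entity_class, toupper(ent$namespace), ent$identifier, sep = ":")
    }
  }
  cls <- function(rel) {
    if (rel %in% c("increases", "directly_increases")) "up"
    else if (rel %in% c("decreases", "directly_decreases")) "down"
    else if (rel == "regulates") "regulates"
    else if (rel %in% c("association", "correlation")) "binds"
    else if (rel == "complex_membership") "membership"
    else "other"
  }
  ei <- kg$edges[i, ]; ej <- kg$edges[j, ]
  si <- gene_key_naive(kg$nodes[[ei$subject]]); oi <- gene_key_naive(kg$nodes[[ei$object]])
  sj <- gene_key_naive(kg$nodes[[ej$subject]]); oj <- gene_key_naive(kg$nodes[[ej$object]])
  if (anyNA(c(si, oi, sj, oj))) return(FALSE)
  ci <- cls(ei$relation); cj <- cls(ej$relation)
  if (ci != cj) return(FALSE)
  if (ci %in% c("binds", "membership")) {
    setequal(c(si, oi), c(sj, oj))
  } else {
    si == sj && oi == oj
  }
}

# A random multigraph over n gene-level protein nodes (plus optional
# non-gene nodes), built directly through the graph API so it is
# independent of the synthetic-fixtures generator.
random_multigraph <- function(n_nodes = 20, n_edges = 40, seed = 1,
                              p_noncausal = 0.2, p_nongene = 0.2) {
  withr::local_seed(seed)
  kg <- bel_kg(name = "random")
  ents <- lapply(seq_len(n_nodes), function(i) {
    if (stats::runif(1) < p_nongene) {
      bel_entity("biological_process", "GO", sprintf("%07d", i))
    } else {
      bel_entity("protein", "HGNC", sprintf("RND%03d", i))
    }
  })
  for (e in ents) kg <- kg_add_entity(kg, e)
  for (j in seq_len(n_edges)) {
    pair <- sample(n_nodes, 2, replace = TRUE)
    rel <- if (stats::runif(1) < p_noncausal) {
      sample(c("association", "correlation", "ontological"), 1)
    } else {
      sample(c("increases", "directly_increases", "decreases",
               "directly_decreases", "regulates"), 1)
    }
    kg <- kg_add_edge(kg, ents[[pair[1]]], ents[[pair[2]]], rel,
                      evidence = sprintf("ev %d", j),
                      citation = as.character(sample(1e7:2e7, 1)))
  }
  kg
}

# Build a corpus data frame in memory (already-parsed form) from simple
# specs: list of lists with fields type, s, o, belief, members, ...
make_corpus <- function(specs) {
  g <- function(sym) sprintf('{"label":"%s","candidates":[{"namespace":"HGNC","identifier":"%s"}]}',
                             sym, sym)
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    members <- if (!is.null(sp$members)) {
      jsonlite::toJSON(lapply(sp$members, function(m) {
        list(label = m, candidates = list(list(namespace = "HGNC", identifier = m)))
      }), auto_unbox = TRUE)
    } else ""
    data.frame(
      uuid = sp$uuid %||% sprintf("u%03d", i),
      statement_type = sp$type,
      belief = as.character(sp$belief %||% 0.9),
      evidence = sp$evidence %||% sprintf("evidence %d", i),
      citation = sp$citation %||% "11111111",
      readers = "reach",
      negated = if (isTRUE(sp$negated)) "true" else "false",
      subject = if (!is.null(sp$s)) g(sp$s) else "",
      object = if (!is.null(sp$o)) g(sp$o) else "",
      members = as.character(members),
      mod_residue = sp$mod_residue %||% "",
      mod_position = sp$mod_position %||% "",
      stringsAsFactors = FALSE
    )
  })
  belcurate:::as_corpus(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run the installed command-line interface; returns exit status and output.
run_cli <- function(...) {
  cli <- system.file("cli", "belcurate", package = "belcurate")
  res <- suppressWarnings(system2("Rscript", c(cli, ...),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(res, "status") %||% 0L, output = paste(res, collapse = "\n"))
}

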