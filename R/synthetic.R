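# Synthetic fixtures: knowledge graphs, statement corpora with planted
# error structure, and simulated curator decisions. All generators are
# pure functions of (config, seed) — they use a private RNG stream and
# never disturb the caller's RNG state.

#' Fixture configuration
#'
#' Defaults mirror the study conditions of the evaluated curation
#' campaign: a 113-gene pool, a corpus triaged to thousands of candidate
#' statements, and planted curation outcomes of 31% correct / 48%
#' correctable error / 21% uncorrectable. The correctable mass is spread
#' over the error taxonomy with named-entity-recognition errors most
#' frequent, followed by subject/object swaps, spurious relations and
#' missed negations. Belief scores default to Beta(5, 2) for faithful
#' extractions and Beta(2, 5) for corrupted ones, so the 0.80 belief
#' threshold has a visible precision effect; set
#' `belief_distribution = "uniform"` for label-independent scores (used
#' when proportions must survive filtering unbiased).
#'
#' @param n_genes genes in the synthetic graph
#' @param n_edges statements in the synthetic graph
#' @param frac_noncausal fraction of non-causal (associative, correlative,
#'   ontological) graph edges
#' @param frac_nongene_nodes number of process/pathology/chemical nodes,
#'   as a fraction of `n_genes`
#' @param corpus_size rows in the synthetic extracted-statement corpus
#' @param belief_distribution `"beta"` (label-dependent, default) or
#'   `"uniform"`
#' @param planted_error_rates named probabilities per error type (the
#'   correctable outcomes)
#' @param planted_correct_rate probability a corpus row is a faithful
#'   extraction
#' @param planted_uncorrectable_rate probability a row cannot be fixed
#' @param frac_duplicate fraction of extra rows duplicating statements
#'   already curated in the graph (exercises the novelty filter; not
#'   counted in the planted outcome proportions)
#' @return a list of class `fixture_config`
#' @export
fixture_config <- function(n_genes = 113L,
                           n_edges = 300L,
                           frac_noncausal = 0.25,
                           frac_nongene_nodes = 0.25,
                           corpus_size = 5000L,
                           belief_distribution = c("beta", "uniform"),
                           planted_error_rates = c(
                             ner_wrong_entity = 0.16,
                             subject_object_swap = 0.10,
                             no_relation_in_evidence = 0.08,
                             negation_missed = 0.06,
                             direct_indirect = 0.04,
                             missing_modification = 0.03,
                             grammar_structure = 0.01
                           ),
                           planted_correct_rate = 0.31,
                           planted_uncorrectable_rate = 0.21,
                           frac_duplicate = 0.05) {
  belief_distribution <- match.arg(belief_distribution)
  rates <- c(planted_correct_rate, planted_error_rates, planted_uncorrectable_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (abs(sum(rates) - 1) > 1e-6) {
    stop(sprintf("planted rates must sum to 1 (got %.4f)", sum(rates)))
  }
  if (!all(names(planted_error_rates) %in% error_types())) {
    stop("planted_error_rates names must come from error_types()")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
      frac_noncausal = frac_noncausal, frac_nongene_nodes = frac_nongene_nodes,
      corpus_size = as.integer(corpus_size),
      belief_distribution = belief_distribution,
      planted_error_rates = planted_error_rates,
      planted_correct_rate = planted_correct_rate,
      planted_uncorrectable_rate = planted_uncorrectable_rate,
      frac_duplicate = frac_duplicate
    ),
    class = "fixture_config"
  )
}

#' Read a fixture configuration from YAML
#' @param path YAML file with any of the [fixture_config()] fields
#' @return a `fixture_config`
#' @export
read_fixture_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$planted_error_rates)) {
    cfg$planted_error_rates <- unlist(cfg$planted_error_rates)
  }
  do.call(fixture_config, cfg)
}

synthetic_gene_symbols <- function(n) sprintf("SYNG%03d", seq_len(n))

NONCAUSAL_POOL <- c("association", "correlation", "ontological")
CAUSAL_POOL <- c("increases", "directly_increases", "decreases",
                 "directly_decreases", "regulates")

#' Generate a synthetic knowledge graph
#'
#' Builds a multigraph over a synthetic gene pool (HGNC-style symbols):
#' every gene gets a protein node, a fraction also RNA nodes and
#' phosphorylated variant nodes, plus process/pathology/chemical nodes per
#' `frac_nongene_nodes`. Edges mix causal and non-causal relations
#' (`frac_noncausal`), each with its own synthetic evidence sentence and
#' citation, so parallel evidences are distinguishable. Deterministic for
#' a fixed seed.
#'
#' @param config a [fixture_config()]
#' @param seed integer seed
#' @return a [bel_kg()]
#' @export
generate_kg <- function(config = fixture_config(), seed = 1L) {
  with_private_seed(seed, {
    genes <- synthetic_gene_symbols(config$n_genes)
    entities <- list()
    for (g in genes) {
      entities[[length(entities) + 1L]] <-
        bel_entity("protein", namespace = "HGNC", identifier = g)
      if (stats::runif(1) < 0.3) {
        entities[[length(entities) + 1L]] <-
          bel_entity("rna", namespace = "HGNC", identifier = g)
      }
      if (stats::runif(1) < 0.15) {
        entities[[length(entities) + 1L]] <- bel_entity(
          "protein", namespace = "HGNC", identifier = g,
          variants = list(bel_modification("phosphorylation", residue = "Ser",
                                           position = sample(50:500, 1)))
        )
      }
    }
    n_other <- round(config$frac_nongene_nodes * config$n_genes)
    other_classes <- c("biological_process", "pathology", "abundance")
    other_ns <- c(biological_process = "GO", pathology = "DOID", abundance = "CHEBI")
    for (j in seq_len(n_other)) {
      klass <- sample(other_classes, 1)
      entities[[length(entities) + 1L]] <- bel_entity(
        klass, namespace = unname(other_ns[klass]),
        identifier = sprintf("%07d", j)
      )
    }

    kg <- bel_kg(name = "synthetic-kg", version = "1.0.0")
    for (e in entities) kg <- kg_add_entity(kg, e)
    keys <- names(kg$nodes)
    for (i in seq_len(config$n_edges)) {
      pair <- sample(length(keys), 2, replace = TRUE)
      noncausal <- stats::runif(1) < config$frac_noncausal
      relation <- if (noncausal) sample(NONCAUSAL_POOL, 1) else sample(CAUSAL_POOL, 1)
      kg <- kg_add_edge(
        kg,
        kg$nodes[[keys[pair[1]]]], kg$nodes[[keys[pair[2]]]], relation,
        evidence = sprintf("Synthetic evidence sentence %d.", i),
        citation = as.character(sample(10000000:29999999, 1))
      )
    }
    kg
  })
}

draw_belief <- function(n, corrupted, distribution) {
  if (distribution == "uniform") return(stats::runif(n))
  ifelse(corrupted,
         stats::rbeta(n, 2, 5),
         stats::rbeta(n, 5, 2))
}

grounding_json <- function(ns, id, label = id, decoy = FALSE) {
  cands <- list(list(namespace = ns, identifier = id))
  if (decoy) {
    cands <- c(cands, list(list(namespace = "CHEBI",
                                identifier = sprintf("%07d", sample(1:9999999, 1)))))
  }
  as.character(jsonlite::toJSON(list(label = label, candidates = cands),
                                auto_unbox = TRUE))
}

#' Generate a synthetic extracted-statement corpus with planted outcomes
#'
#' Emits `corpus_size` machine-read statements over the graph's genes.
#' Each row draws a ground-truth label from the planted proportions:
#' `correct` (a faithful extraction of a new relation), one of the
#' configured error types (the corruption is actually applied — swapped
#' subject/object, a decoy entity, a dropped negation word, a
#' direct/indirect flip, a dropped modification), or `uncorrectable`
#' (evidence with no extractable relation). An additional
#' `frac_duplicate` of rows replicate statements already curated in the
#' graph to exercise the novelty filter; they carry the label
#' `duplicate` and are excluded from the planted proportions. Belief
#' scores are drawn per the configured distribution (corrupted rows
#' stochastically lower under the beta default). Byte-identical output for
#' a fixed seed.
#'
#' @param kg a [bel_kg()] from [generate_kg()]
#' @param config a [fixture_config()]
#' @param seed integer seed
#' @return list with `corpus` (a [bel_corpus]) and `truth` (data frame:
#'   `uuid`, `label`, `true_bel` — the statement a perfect curator would
#'   write for correctable rows)
#' @export
generate_corpus <- function(kg, config = fixture_config(), seed = 1L) {
  stopifnot(kg_n_nodes(kg) > 0)
  with_private_seed(seed + 1L, {
    genes <- unique(stats::na.omit(vapply(names(kg$nodes), function(k) {
      ent <- kg$nodes[[k]]
      if (is_gene_level(ent)) canonical_key(ent) else NA_character_
    }, character(1))))
    if (!length(genes)) stop("graph contains no gene-level nodes")
    labels_pool <- c("correct", names(config$planted_error_rates), "uncorrectable")
    probs <- c(config$planted_correct_rate, unname(config$planted_error_rates),
               config$planted_uncorrectable_rate)

    n <- config$corpus_size
    n_dup <- round(config$frac_duplicate * n)
    type_pool <- c("activation", "inhibition", "phosphorylation",
                   "other_modification", "complex_formation", "regulate_amount")
    type_probs <- c(0.33, 0.25, 0.18, 0.06, 0.08, 0.10)

    rows <- vector("list", n + n_dup)
    truth <- vector("list", n + n_dup)
    causal_edges <- which(kg$edges$causal)

    for (i in seq_len(n + n_dup)) {
      uuid <- sprintf("stmt-%05d", i)
      is_dup <- i > n && length(causal_edges) > 0
      label <- if (is_dup) "duplicate" else sample(labels_pool, 1, prob = probs)
      type <- sample(type_pool, 1, prob = type_probs)
      mod_residue <- ""
      mod_position <- ""
      members <- ""
      negated <- "false"

      if (is_dup) {
        # replicate an already-curated causal edge as an activation statement
        e <- kg$edges[sample(causal_edges, 1), ]
        s_ent <- kg$nodes[[e$subject]]
        o_ent <- kg$nodes[[e$object]]
        sk <- strsplit(canonical_key(s_ent), ":", fixed = TRUE)[[1]]
        ok <- strsplit(canonical_key(o_ent), ":", fixed = TRUE)[[1]]
        type <- if (e$relation %in% c("decreases", "directly_decreases"))
          "inhibition" else if (e$relation == "regulates") "regulate_amount" else "activation"
        subject_js <- grounding_json(sk[1], sk[2])
        object_js <- grounding_json(ok[1], ok[2])
        true_bel <- NA_character_
      } else {
        pick <- sample(genes, min(3, length(genes)))
        s_parts <- strsplit(pick[1], ":", fixed = TRUE)[[1]]
        o_parts <- strsplit(pick[2], ":", fixed = TRUE)[[1]]
        subject_js <- grounding_json(s_parts[1], s_parts[2])
        object_js <- grounding_json(o_parts[1], o_parts[2])
        if (type == "phosphorylation") {
          mod_residue <- sample(c("Ser", "Thr", "Tyr"), 1)
          mod_position <- as.character(sample(10:900, 1))
        }
        if (type == "complex_formation") {
          k_members <- sample(2:3, 1)
          mem <- lapply(pick[seq_len(k_members)], function(g) {
            p <- strsplit(g, ":", fixed = TRUE)[[1]]
            list(label = p[2],
                 candidates = list(list(namespace = p[1], identifier = p[2])))
          })
          members <- as.character(jsonlite::toJSON(mem, auto_unbox = TRUE))
        }
        # the statement a perfect curator would assert from the evidence
        true_keyword <- switch(type,
          activation = "increases", inhibition = "decreases",
          phosphorylation = "increases", other_modification = "increases",
          regulate_amount = "regulates", complex_formation = "association"
        )
        true_bel <- sprintf("p(%s:%s) %s p(%s:%s)",
                            s_parts[1], s_parts[2], true_keyword,
                            o_parts[1], o_parts[2])
        # apply the planted corruption so the corpus row really is wrong
        if (label == "subject_object_swap") {
          tmp <- subject_js; subject_js <- object_js; object_js <- tmp
        } else if (label == "ner_wrong_entity") {
          subject_js <- grounding_json(s_parts[1], s_parts[2], decoy = TRUE)
          # the reader picked the decoy; record it by shuffling candidates
          js <- jsonlite::fromJSON(subject_js, simplifyVector = FALSE)
          js$candidates <- rev(js$candidates)
          subject_js <- as.character(jsonlite::toJSON(js, auto_unbox = TRUE))
        } else if (label == "missing_modification") {
          mod_residue <- ""; mod_position <- ""
        }
      }

      evidence <- switch(label,
        uncorrectable = sprintf(
          "Synthetic filler sentence %d with no extractable relation.", i),
        negation_missed = sprintf(
          "Synthetic evidence %d: the subject did not regulate the object.", i),
        sprintf("Synthetic evidence %d describing a %s event.", i, type)
      )
      corrupted <- !label %in% c("correct", "duplicate")
      rows[[i]] <- data.frame(
        uuid = uuid, statement_type = type,
        belief = sprintf("%.6f", draw_belief(1, corrupted, config$belief_distribution)),
        evidence = evidence,
        citation = as.character(sample(10000000:29999999, 1)),
        readers = paste(sample(c("reach", "sparser"), sample(1:2, 1)), collapse = ","),
        negated = negated,
        subject = subject_js, object = object_js, members = members,
        mod_residue = mod_residue, mod_position = mod_position,
        stringsAsFactors = FALSE
      )
      truth[[i]] <- data.frame(uuid = uuid, label = label,
                               true_bel = if (is_dup) NA_character_ else true_bel,
                               stringsAsFactors = FALSE)
    }
    corpus <- as_corpus(do.call(rbind, rows))
    list(corpus = corpus, truth = do.call(rbind, truth))
  })
}

#' Simulate a perfect curator filling a sheet
#'
#' Applies the marking protocol mechanically from the ground-truth labels:
#' every row is checked; faithful rows are marked correct; rows with a
#' fixable planted error are marked changed, annotated with the planted
#' error type and given the true statement as the correction;
#' uncorrectable rows get neither mark. Rows whose uuid has no truth label
#' are a misalignment error.
#'
#' @param sheet sheet data frame (as written by [generate_sheets()]) or a
#'   path to one
#' @param truth the `truth` table from [generate_corpus()]
#' @param seed integer seed (used only to pick a synthetic curator name
#'   per sheet)
#' @return the filled sheet data frame
#' @export
simulate_curator <- function(sheet, truth, seed = 1L) {
  if (is.character(sheet)) {
    sheet <- utils::read.delim(sheet, stringsAsFactors = FALSE,
                               colClasses = "character", quote = "",
                               na.strings = NULL)
  }
  idx <- match(sheet$uuid, truth$uuid)
  if (anyNA(idx)) {
    stop(sprintf("sheet and truth labels are misaligned: %d row(s) have no label",
                 sum(is.na(idx))))
  }
  labels <- truth$label[idx]
  with_private_seed(seed + 2L, {
    curator <- sprintf("synthetic-curator-%d", sample(1:5, 1))
    sheet$checked <- "x"
    sheet$correct <- ifelse(labels %in% c("correct", "duplicate"), "x", "")
    fixable <- labels %in% error_types()
    sheet$changed <- ifelse(fixable, "x", "")
    sheet$error_type <- ifelse(fixable, labels, "")
    sheet$corrected_bel <- ifelse(fixable, truth$true_bel[idx], "")
    sheet$curator <- curator
  })
  sheet
}
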