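# Knowledge-graph model: parsing, writing, canonical triples.

test_that("a toy document parses into the expected graph", {
  doc <- c(
    'SET DOCUMENT Name = "toy"',
    'DEFINE NAMESPACE HGNC AS URL "http://h"',
    'DEFINE NAMESPACE GO AS URL "http://g"',
    'SET Citation = "30718"',
    'SET Evidence = "MAPT induces apoptosis."',
    'p(HGNC:MAPT) increases bp(GO:"apoptotic process")',
    'UNSET Evidence',
    'SET Evidence = "GSK3B phosphorylates MAPT."',
    'p(HGNC:GSK3B) directlyIncreases p(HGNC:MAPT, pmod(Ph, Ser, 396))',
    'UNSET ALL',
    'r(HGNC:APP) association p(HGNC:GSK3B)'
  )
  kg <- parse_bel_script(doc)
  expect_equal(kg_n_edges(kg), 3)
  expect_equal(kg_n_nodes(kg), 5)
  expect_equal(nrow(kg$errors), 0)
  expect_equal(kg$metadata$name, "toy")
  expect_equal(kg$edges$relation, c("increases", "directly_increases", "association"))
  expect_equal(kg$edges$citation, c("30718", "30718", ""))
  expect_equal(kg$edges$evidence[2], "GSK3B phosphorylates MAPT.")
})

test_that("a malformed relation keyword yields an error record, not an edge", {
  doc <- c(
    'DEFINE NAMESPACE HGNC AS URL "http://h"',
    'p(HGNC:MAPT) explodes p(HGNC:APP)'
  )
  kg <- parse_bel_script(doc)
  expect_equal(kg_n_edges(kg), 0)
  expect_equal(nrow(kg$errors), 1)
  expect_equal(kg$errors$line, 2L)
  expect_match(kg$errors$message, "explodes")
})

test_that("undeclared namespaces are warnings, not errors", {
  kg <- parse_bel_script(c(
    'DEFINE NAMESPACE HGNC AS URL "http://h"',
    'p(HGNC:MAPT) increases p(MGI:Mapt)'
  ))
  expect_equal(kg_n_edges(kg), 1)
  expect_equal(nrow(kg$warnings), 1)
  expect_match(kg$warnings$message, "MGI")
})

test_that("annotation SET/UNSET blocks are captured per statement", {
  kg <- parse_bel_script(c(
    'SET Citation = {"PubMed", "999"}',
    'SET Confidence = "High"',
    'SET CellLine = "SH-SY5Y"',
    'p(HGNC:A) increases p(HGNC:B)',
    'UNSET Confidence',
    'p(HGNC:A) decreases p(HGNC:C)'
  ))
  expect_equal(kg$edges$citation, c("999", "999"))
  ann1 <- kg$edges$annotations_list[[1]]
  ann2 <- kg$edges$annotations_list[[2]]
  expect_equal(ann1[["Confidence"]], "High")
  expect_equal(ann1[["CellLine"]], "SH-SY5Y")
  expect_false("Confidence" %in% names(ann2))
  expect_equal(ann2[["CellLine"]], "SH-SY5Y")
})

test_that("parse/write round-trip preserves nodes, edges and annotations", {
  kg <- random_multigraph(n_nodes = 50, n_edges = 120, seed = 42)
  # attach some annotations to exercise the SET blocks
  kg$edges$annotations_list[[1]] <- c(Confidence = "High", Species = "9606")
  txt <- write_bel_script(kg)
  kg2 <- parse_bel_script(txt)
  expect_equal(nrow(kg2$errors), 0)
  expect_setequal(names(kg2$nodes), names(kg$nodes))
  key <- function(e) paste(e$subject, e$relation, e$object, e$citation, e$evidence)
  expect_setequal(key(kg2$edges), key(kg$edges))
  # annotation survives
  i <- which(key(kg2$edges) == key(kg$edges)[1])
  expect_equal(kg2$edges$annotations_list[[i]][["Confidence"]], "High")
  # write o parse is idempotent
  expect_identical(write_bel_script(parse_bel_script(txt)), txt)
})

test_that("act() wrappers and quoted identifiers round-trip", {
  doc <- c(
    'SET Evidence = "says \\"quoted\\" things"',
    'p(HGNC:X) increases act(p(HGNC:Y))',
    'act(p(HGNC:Y)) decreases bp(GO:"cell death")'
  )
  kg <- parse_bel_script(doc)
  expect_equal(nrow(kg$errors), 0)
  expect_true(kg$edges$object_activity[1])
  expect_true(kg$edges$subject_activity[2])
  expect_equal(kg$edges$evidence[1], 'says "quoted" things')
  kg2 <- parse_bel_script(write_bel_script(kg))
  expect_equal(nrow(kg2$errors), 0)
  expect_true(kg2$edges[kg2$edges$relation == "increases", "object_activity"])
})

test_that("causal flag is a pure function of the relation", {
  kg <- random_multigraph(n_nodes = 15, n_edges = 60, seed = 3)
  causal_set <- c("increases", "directly_increases", "decreases",
                  "directly_decreases", "regulates")
  expect_equal(kg$edges$causal, kg$edges$relation %in% causal_set)
  expect_false(relation_is_causal("complex_membership"))
  expect_false(relation_is_causal("has_variant"))
})

test_that("canonical triples collapse variants and directness", {
  gsk <- bel_entity("protein", "HGNC", "GSK3B",
                    variants = list(bel_modification("phosphorylation")))
  mapt <- bel_entity("protein", "HGNC", "MAPT",
                     variants = list(bel_modification("phosphorylation", "Ser", 396)))
  tr <- canonical_triple(gsk, mapt, "directly_increases")
  expect_equal(tr$subject_key, "HGNC:GSK3B")
  expect_equal(tr$relation_class, "up")
  expect_equal(tr$object_key, "HGNC:MAPT")
  expect_true(tr$comparable)
  # reflexivity and idempotence under repeated collapsing
  expect_identical(tr, canonical_triple(gsk, mapt, "directly_increases"))
  stripped_s <- bel_entity("protein", "HGNC", "GSK3B")
  stripped_o <- bel_entity("protein", "HGNC", "MAPT")
  expect_equal(canonical_triple(stripped_s, stripped_o, "increases")$key, tr$key)
  # ungrounded endpoints are flagged non-comparable
  un <- canonical_triple(bel_entity("protein", label = "mystery"), mapt, "increases")
  expect_false(un$comparable)
  expect_true(is.na(un$key))
})

test_that("triple equality partitions edges like a brute-force comparator", {
  kg <- random_multigraph(n_nodes = 8, n_edges = 20, seed = 11, p_nongene = 0.3)
  keys <- kg_triple_keys(kg)
  n <- kg_n_edges(kg)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same_by_triple <- !is.na(keys[i]) && !is.na(keys[j]) && keys[i] == keys[j]
      expect_equal(same_by_triple, oracle_edges_equivalent(kg, i, j),
                   info = sprintf("edges %d vs %d", i, j))
    }
  }
})

test_that("exact duplicate statements are merged; distinct evidences are kept", {
  a <- bel_entity("protein", "HGNC", "A")
  b <- bel_entity("protein", "HGNC", "B")
  kg <- bel_kg()
  kg <- kg_add_edge(kg, a, b, "increases", evidence = "e", citation = "1")
  kg <- kg_add_edge(kg, a, b, "increases", evidence = "e", citation = "1")
  expect_equal(kg_n_edges(kg), 1)
  kg <- kg_add_edge(kg, a, b, "increases", evidence = "other", citation = "1")
  expect_equal(kg_n_edges(kg), 2)
})

test_that("empty and single-edge graphs write valid documents", {
  expect_equal(sum(nzchar(write_bel_script(bel_kg()))), 2)  # header only
  kg <- kg_add_edge(bel_kg(), bel_entity("protein", "HGNC", "A"),
                    bel_entity("protein", "HGNC", "B"), "increases",
                    evidence = "e", citation = "1")
  txt <- write_bel_script(kg)
  expect_equal(sum(grepl(" increases ", txt)), 1)
})
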