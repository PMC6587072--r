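---
title: "Methods: rational enrichment and re-curation of BEL knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rational enrichment and re-curation of BEL knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belcurate)
```

## The problem

A curated knowledge graph in the Biological Expression Language (BEL)
represents causal, correlative and associative relations between grounded
biological entities, each edge backed by an evidence sentence and a
citation. Two failure modes accumulate over a graph's life: quality debt
(statements curated without inter-annotator agreement, drifting
terminologies, missing annotations) and coverage debt (the literature
outruns the curators). `belcurate` implements one workflow for each: a
re-curation quality gate, and a rational-enrichment loop that spends
curator time where the graph is thinnest.

## The graph model

The graph is a directed multigraph. Nodes are entities with a class
(gene, rna, microrna, protein, chemical abundance, complex, family,
biological process, pathology, reaction), a `(namespace, identifier)`
grounding and optional variants (post-translational modifications,
sequence variants; permitted on gene/rna/protein only). Edges carry a
relation type, an evidence string, a citation and free-form annotations.
The causal flag is a pure function of the relation: the four
increase/decrease forms and `regulates` are causal; membership, variant,
associative, correlative and ontological relations are not. Parallel
edges between the same endpoints are allowed exactly when (relation,
citation, evidence) differ — each independent evidence is its own unit of
knowledge — and statement identity is the fingerprint of (subject,
relation, object, citation, evidence), which is what lets sheets, merges
and re-parses agree on which statement is which.

The reader/writer covers a deliberate BEL 2.0 subset: `p()`, `g()`,
`r()`, `m()`, `a()`, `complex()`, `bp()`, `path()`, `act()`, `pmod()`,
`var()`, with reactions parsed as opaque nodes. Lists, translocations and
fusions are out of scope; documents using them will produce per-line
error records rather than silent loss. One dialect note: the writer emits
the keyword `correlation` for sign-free correlative edges (the parser
also accepts `positiveCorrelation`/`negativeCorrelation`, folding the
sign away, since downstream processing only distinguishes causal from
non-causal).

## Preprocessing and the information-density metric

Enrichment operates on a reduced view of the graph, produced by
`preprocess()`:

1. remove excluded entity classes and their incident edges (default:
   chemical abundances, reactions, pathologies, biological processes —
   the exclusion list is configurable but may never contain genes);
2. remove non-causal edges;
3. collapse the central dogma: every RNA, microRNA, protein or variant
   node is rewired onto its gene's canonical key, so all products of a
   gene pool their causal information.

"Gene-level" here includes protein families (kept under their family
key — they function as gene groups) and, for entities with only a protein
grounding, the protein key itself; composed complexes cannot be reduced
to a single gene and are dropped with the excluded classes. Rewired
duplicates with identical (canonical triple, citation, evidence) merge,
and self-loops arising from collapsing (autoregulation,
autophosphorylation) are kept — they are causal information — and
contribute 2 to the degree. The operation is idempotent, which the test
suite checks by property.

The information density of gene *g* is then in-degree plus out-degree in
this reduced multigraph, counting parallel evidences (a switch,
`count_evidences = FALSE`, counts unique collapsed relations instead for
users who prefer relation-level coverage; evidence counting is the
default because each evidence is independently useful to an analyst).
Ranking is ascending — the least-known genes are curated first — with
lexicographic tie-breaks on the canonical key so the order is a
deterministic total order. Per round the first *k* = 30 genes are taken;
passing previous rounds' genes through `exclude` makes the procedure
iterative.

## Corpus triage

The statement corpus stands in for a large-scale machine-reading dump:
one row per extracted relation with candidate groundings (JSON),
statement type, a belief score in [0, 1], evidence, citation and reader
tags. Belief scores are consumed, never computed. Three filters run in
order:

* **query** — keep statements any of whose candidate groundings matches a
  prioritised gene key;
* **novelty** — drop statements whose canonical gene-level triple
  (endpoints collapsed, increase forms folded to `up`, decrease forms to
  `down`, direction-free classes compared with sorted endpoints) already
  exists in the *un*-preprocessed curated graph. Gene-collapsed
  comparison is the default granularity: a phosphorylation statement
  duplicating an existing protein-level increase between the same genes
  adds no curation value. Ungroundable statements are kept and flagged —
  dropping them silently would hide reader failures from the curator;
* **belief** — keep scores `>= 0.80` by default (the boundary stays: a
  0.80 statement survives a 0.80 threshold). Missing scores are treated
  as 0 and logged, a deliberately conservative choice favouring
  precision.

## Assembly semantics

`assemble_statements()` turns surviving statements into candidate BEL
edges: activation/inhibition become (directly-)increases/decreases onto
`act(object)`; modifications become an edge onto the modified protein
node plus a `hasVariant` edge from the reference protein; complex
formation over *n* members becomes a composed complex node with *n*
membership edges and *n(n−1)* pairwise bidirectional association records;
amount regulation becomes a plain `regulates` edge. Two defaults encode
hard-won conventions: the directness default is *indirect* (plain
`increases`), because direct physical contact is rarely decidable from
text, and `act()` is never wrapped around biological processes or
pathologies — activity is reserved for physical entities — with the
downgrade logged. Negated statements are skipped with a record rather
than emitted as negative assertions. Multiple modifications on one
statement yield a single modified node with all modifications and one
`hasVariant` edge (minimal-node principle). Every emitted edge carries
its statement's uuid, evidence and citation.

## Sheets and the marking protocol

Sheets are tab-separated (diff-able under version control; the canonical
format) with the fixed header `uuid, gene, reference, evidence, bel,
checked, correct, changed, error_type, corrected_bel, curator`. A
case-insensitive literal `x` is the only truthy mark. Ingest enforces the
protocol: marks imply `checked`; `correct` and `changed` are exclusive;
`error_type` requires a changed or uncorrectable row and must come from
the controlled vocabulary; curator-added rows — extra statements sharing
a known uuid's provenance — must be changed-only. Violations come back as
structured findings with row numbers and rule identifiers; valid rows
classify into exactly one of correct / changed / uncorrectable /
unchecked. A statement matching several queried genes is sheeted once,
under its first matching gene, to avoid duplicate curation effort.

## Quality statistics

`summarize_curation()` excludes unchecked rows from every denominator.
Percentages are kept at full precision internally and printed to one
decimal; throughput (`edges / (hours × 60)`) is likewise full precision,
conventionally reported to two decimals. The recovery rate is defined as
(correct + changed) / evaluated, so it equals the sum of the correct and
changed percentages identically. The effort comparison between top-*k*
and bottom-*k* accuracy genes uses Welch's t-test by default — the
pooled-variance test assumes equal variances, which per-gene curation
times rarely satisfy — with `var_equal = TRUE` available for the
classical variant.

## Re-curation quality gate

`check_required_annotations()` reports one violation per edge missing a
required annotation (typically `Confidence`), and the CLI's
`qc check` exits non-zero on any violation, which is the whole CI
integration contract. Confidence levels are stored as the literal strings
`None`/`Low`/`Medium`/`High`/`Very High` (with the space) for document
fidelity; the ordinal order lives in `confidence_levels()`. The
transitions form a small state machine: the second curator can delete a
nonsense evidence (together with all statements sharing that evidence —
same-evidence scope is the default, same-citation available by flag,
since "related statements" is genuinely ambiguous), set Low for unclear
biology, fix a wrong statement (Medium), or accept an assertable one
(High). Only the third curator's agreement promotes Medium/High to Very
High; the test suite verifies over random action sequences that no other
path reaches it. Terminology drift is handled by a user-supplied
two-column old→new mapping table applied to the graph, not by live
lookups.

## The synthetic generators

The fixture module emulates the statistical structure of a real curation
campaign, not its text. Defaults are the study conditions: a 113-gene
pool, planted outcome proportions of 0.31 correct / 0.48 correctable /
0.21 uncorrectable, correctable mass spread over the error taxonomy with
NER errors most frequent, and belief scores drawn from Beta(5, 2) for
faithful rows versus Beta(2, 5) for corrupted rows so that the 0.80
threshold visibly trades recall for precision. Corruptions are actually
applied (swapped endpoints, decoy groundings, dropped negation words,
dropped modifications), and a small fraction of rows (5%) duplicate
already-curated statements to exercise the novelty filter; these carry a
separate `duplicate` label and sit outside the planted proportions. All
generators draw from a private RNG stream, so they are pure functions of
(config, seed) and never disturb the caller's RNG.

What the generators do *not* emulate: linguistically realistic evidence
sentences, reader-specific error signatures, citation clustering, or the
long-tailed per-gene statement counts of real literature. Green tests
therefore demonstrate the bookkeeping and the statistical machinery, not
reader accuracy on real text.

## Numerical and design choices

* **Closed-loop check.** The master integration test runs the full
  pipeline on a 5000-statement corpus and requires the recovered outcome
  proportions to land within 2 percentage points of the plants. For that
  check the belief scores are label-independent (`uniform`) and the
  belief threshold is 0: proportion recovery is only a meaningful test
  when every filter stage is outcome-blind, and the label-dependent beta
  default would (correctly, but confoundingly) enrich for faithful rows.
  The precision effect of the beta default is tested separately.
* **Problem sizes.** Property tests use 100 random multigraphs of up to
  50 nodes; the state-machine exploration runs 10 000 random action
  sequences; the closed loop uses 5000 corpus rows. These sizes give the
  binomial checks 3-sigma headroom while keeping the whole suite in a
  few minutes on one core.
* **Determinism.** Sheet files and written BEL documents are sorted
  (citation, then statement text) so regeneration is byte-identical;
  ranking ties break lexicographically; a round's manifest plus its seed
  reproduce the round exactly.
* **Statement fingerprints.** Identifiers are minted with a small
  polynomial string hash (base 131 mod 2³¹−1, exact in doubles) over the
  identity tuple — collision risk is negligible at campaign scale and the
  scheme has no dependencies.
* **Degenerate inputs.** Empty graphs preprocess to empty graphs; a
  report over zero evaluated rows flags its percentages as undefined
  (`NA`, never `NaN`); `throughput()` rejects non-positive hours;
  unparseable corrected statements during merge produce row-level error
  records and never abort the merge.

## Known limitations

The BEL subset excludes list objects, translocations and fusions;
reaction nodes are opaque. Namespaces are validated only against the
document's declarations — grounding quality is the corpus producer's
responsibility. Multi-curator conflicts on the same sheet resolve
last-writer-wins at ingest. The information-density function is
degree-based by design; alternative centralities (or prioritising edges
between low- and high-density nodes) would slot into the same ranking
interface but are not implemented.
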