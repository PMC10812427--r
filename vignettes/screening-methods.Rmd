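---
title: "Screening chromosome proteomes for cell-surface-accessible targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chromosome proteomes for cell-surface-accessible targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfscreen)
```

## The problem

Immunological separation of X- from Y-chromosome-bearing spermatozoa needs
protein targets that are (a) encoded by one sex chromosome and (b) physically
reachable by an antibody from outside the cell. `surfscreen` implements an
in-silico screen for such targets over a chromosome-scoped proteome, plus a
cross-species tool that asks whether targets selected in one species (e.g.
human) have counterparts in another (e.g. rabbit). Every stage operates on
plain files — UniProt-style proteome tables, BioMart-style transcript
mappings, eggNOG-mapper-style annotation tables, topology-predictor output,
FASTA — so the whole pipeline runs offline and is testable end to end.

## Redundancy filtering

Reference proteomes are heavily redundant: several UniProt entries can be
products of one gene, and one entry can be mapped to several transcripts.
`filter_redundant()` reduces a raw chromosome proteome to at most one entry
per gene in three rules:

1. entries whose transcripts have no associated gene are dropped (they
   cannot be gene-deduplicated);
2. among entries sharing a gene, the reviewed entry wins; failing that, the
   entry whose transcript is the Ensembl-canonical one; failing that, the
   lexicographically smallest accession (the tie-break is our choice — the
   procedure needs *some* deterministic rule for reproducible audits, and
   accession order is stable and visible in the data);
3. an entry mapped to several transcripts keeps one, preferring the
   canonical transcript.

Two reviewed entries for one gene are resolved by the tie-break with a
warning rather than an error: the condition is unusual but not impossible in
real exports. Every dropped accession is recorded in a `filter_audit` whose
counts reconcile exactly with the input; filtering is idempotent.

## Annotation merge and evidence tracking

Cellular-localisation evidence is drawn from two sources: the entry's own
GO annotations and GO terms transferred by orthology (eggNOG-mapper-style
output). Orthology transfers are accepted only from one-to-one orthologs
passing all quality thresholds — e-value ≤ 0.001, bit-score ≥ 60, identity,
query and subject coverage ≥ 80% — with all thresholds inclusive: the tools
describe them as minima/maxima, and the inclusive reading is the
conventional one. GO IDs on accepted rows lacking experimental evidence are
stripped (names and descriptions are kept, since naming does not require
experimental support while localisation transfer does).

`merge_annotations()` forms the per-protein union of both GO sources with
per-ID source bookkeeping and an experimentally-supported subset
(UniProt evidence codes in the configurable experimental set — default
EXP/IDA/IPI/IMP/IGI/IEP plus the high-throughput family — or eggNOG rows
flagged as experimental). Proteins without a topology prediction carry an
explicit missing flag.

## The target rule

A fixed catalogue of cellular-component GO IDs drives the decision
(`go_catalog()`). Classes split into two disjoint groups:

* **surface classes** (cell surface; external, anchored-external,
  integral-external components of the plasma membrane; external side of cell
  wall / outer membrane): annotation alone makes a protein a candidate
  target, whatever its topology;
* **membrane classes** (plasma membrane, anchored/integral component of the
  plasma membrane, extracellular space): annotation makes a protein a
  target only when topology prediction says it is transmembrane.

A protein is *of interest* (plasma-membrane associated) when any catalogue
ID matches, or when its only relevant annotation is extracellular space and
it is transmembrane. A protein is a *target* when a surface-class ID
matches, or a membrane-class ID matches on a transmembrane protein.

Three deliberate choices:

* **No ontology expansion.** Only the exact catalogue IDs trigger. The
  catalogue is a curated topological shortlist (it even retains an obsolete
  anchored-component term because it encodes a topology), and descendant
  expansion would silently change its meaning.
* **Beta-barrels count as transmembrane** in the membrane branch. The rule
  asks for "transmembrane", not "alpha-helical"; in mammalian screens no
  beta-barrel reaches the rule in practice, so this is a completeness
  decision with no effect on results.
* **Missing topology is non-transmembrane.** Conservative: a membrane-class
  annotation without a positive transmembrane prediction is not enough.
  Such proteins are flagged so users can revisit them.

The five-way topology classification (TM, TM+SP, BETA, GLOB, GLOB+SP) and
the printed table labels (TM, SP+TM, GLOB, SP) interconvert through a single
fixed mapping (`topology_from_label()`), so published per-protein tables can
be re-encoded and re-classified; `read_printed_target_table()` substitutes
one representative GO ID per printed class.

## Overrepresentation statistic

`overrepresentation_test()` is a flat, one-sided Fisher exact test per
annotated term with fold enrichment `(k/n)/(K/N)` and Bonferroni adjustment
`min(1, m·p)`, `m` = number of terms tested in the run (shared between the
over- and under-direction, which are reported as separate rows — sidedness
conventions differ between services, so both are exposed). Tail
probabilities come from the numerically stable log-space hypergeometric
distribution function. No term-hierarchy elimination is applied: the
statistic, not any particular annotation service, is in scope here, and the
reference annotation is always a user-supplied input.

## Alignment and the similarity statistic

Cross-species comparisons use true global (Needleman–Wunsch) alignment with
affine gaps, BLOSUM62, gap open −11 and gap extension −1 — the protein-BLAST
conventions. Numerical choices:

* a gap of length `g` costs `−11 − (g − 1)`; end gaps are penalized like
  internal gaps (a semiglobal variant is available behind
  `penalize_end_gaps = FALSE` since library defaults differ on this point);
* the traceback is deterministic: diagonal over up over left at every tie;
* residues outside BLOSUM62 (U, O, J) score a fixed −1 against everything;
  ambiguity codes already in the matrix (B, Z, X) use its own rows; anything
  else is an error naming the offending position;
* **"number of indels" means gap columns**: the similarity statistic is
  `100 × matches / (alignment length − gap columns)`, i.e. percent identity
  over residue–residue columns. This reading keeps the statistic within
  [0, 100] and gives it a clean closed form under substitution-only
  divergence (`100(1 − p)` at substitution rate `p`), which the recovery
  tests exploit. Counting gap *events* instead is representable but not the
  default.

The aligner is validated two independent ways: exhaustive enumeration of
all global alignments for short pairs (`enumerate_global_score()`, also
exported as a validation utility), and score agreement with an independent
library implementation under the equivalent gap parameterisation.

Isoform choice for each gene/species mirrors common RefSeq practice:
`isoform X1` if present, else `isoform 1`, else the longest product, ties by
smallest RefSeq ID.

## Cross-species mapping and curation

`map_targets_across_species()` classifies each reference-species target
gene against the query species: `common_target` (already in the query
species' own target list), `additional_candidate` (present in the query
proteome but not among its targets), or `unresolved` (no product found).
Candidates below 70% similarity are *flagged for review, never
auto-excluded* — divergence alone is not disqualifying. `apply_curation()`
then codifies the manual rules, in order: entries removed from the source
database; genes placed on a chromosome other than the target chromosome;
alias mappings onto a product another gene owns as its primary name; and
non-orthologs — exempted when the ordered flanking-gene lists (three genes
each side by default) are identical, since conserved synteny is the
classical rescue for an incomplete ortholog call. Entries with no gene name
can still be matched to candidates through their orthology-assigned names
(`match_unnamed_via_eggnog()`), each match flagged for follow-up
verification. The comprehensive target list is the gene-level union of
first-pass targets and surviving additions, deduplicated case-insensitively
by gene name with accession fallback.

A live NCBI E-utilities adapter (`fetch_ncbi_store()`) can populate the
local sequence store, with rate limiting and on-disk caching; all analysis
functions and all tests operate on the local store only.

## What the synthetic generator emulates — and what it does not

`generate_proteome()` writes a complete input set with a ground-truth
ledger. Its defaults are the study conditions: duplicate-entry rate 0.395
(the duplicate fraction of the rabbit reference proteome; the human one
showed 0.62), one canonical transcript per gene, shifted-geometric
transcript counts (mean 1.8), 40% reviewed entries, 30% of genes planted
with a catalogue annotation (half of those surface-class), 25%
transmembrane, sequences 60–400 residues — values chosen once to exercise
every rule branch at realistic sparsity. Planted targets satisfy the target
rule by construction and planted non-targets violate it, so stage outputs
can be compared with the ledger *exactly*. `generate_crossmap_fixture()`
plants every curation scenario at least once.

The generator does **not** emulate: GO DAG structure (annotations are flat
IDs), realistic amino-acid composition (uniform residues are sufficient for
rule-based stages and keep the similarity closed form exact), phylogenetic
sequence evolution (substitutions are uniform among 19 alternatives,
applied before single-residue indels so column identity has a closed form),
or database-version drift. Consequently, passing ledger tests shows the
*rules* are implemented faithfully; it does not certify counts on any real
proteome release, which depend on the database versions used.

## Problem sizes and tolerances in the shipped checks

The test suite regenerates all fixtures in code: the end-to-end ledger check
uses 500 genes; the alignment/enumeration equivalence uses 10,000 random
pairs of length ≤ 6 over a reduced alphabet; the Fisher/enumeration
equivalence covers every contingency table with reference size ≤ 12 at
1e−12; the null-calibration check uses 500 simulated draws of 2,000 from a
reference of 10,000 over 10 terms — sizes at which the hypergeometric tail
is fine-grained enough that the discrete rejection rate can sit inside a
binomial 99% band around the nominal 0.05 (with small tables the test's
conservativeness dominates); ortholog similarity recovery uses 100 pairs of
length 500 at 10% substitution, where the mean similarity must fall within
one point of 90. Published per-protein tables bundled as plain-text fixtures
are re-encoded and re-classified, reproducing their printed target counts
exactly; the four published cross-species similarity benchmarks are
accession-based and require retrieving the named sequences from UniProt/NCBI,
so that check runs only with network access.

## Known limitations

* Gene-level deduplication keeps exactly one entry per gene; legitimate
  distinct isoform entries of one gene are collapsed by design.
* The screen is annotation-bound: a surface protein with no catalogue GO ID
  and no transmembrane prediction cannot be found.
* The similarity statistic is identity-based; no similarity-matrix
  weighting of near-conservative substitutions.
* Orthology is an input (curation records), never re-inferred.
* Alignment memory is quadratic in sequence length; fine for proteins, not
  intended for very long concatenations.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_proteome(sim_config(n_genes = 100, seed = 1))
cfg <- pipeline_config(
  proteome = sim$paths$proteome, mapping = sim$paths$mapping,
  topology = sim$paths$topology, eggnog = sim$paths$eggnog,
  sperm_list = sim$paths$sperm
)
res <- run_pipeline(cfg)
res$manifest$counts
```
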