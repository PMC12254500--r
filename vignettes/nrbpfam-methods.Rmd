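---
title: "Methods: homolog filtering, triad classification and divergence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homolog filtering, triad classification and divergence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrbpfam)
```

# Scope

`nrbpfam` implements the computational core of a study of a vertebrate
pseudokinase paralog family (NRBP1/NRBP2): curating a set of orthologous
sequences from pairwise-search hit tables, classifying family members as
pseudokinases from their catalytic-triad residues, testing whether one
paralog clade diverges faster than the other, and quantifying bench
readouts (RIP-qPCR enrichment, ΔΔCt expression, retrotransposition
activity). A synthetic-data generator with planted ground truth makes
every stage testable without any network access or external databases.

All sequence coordinates in this package are 1-based and inclusive, the
convention of BLAST tabular output and of `IRanges`.

# Ortholog filtering

`filter_chain()` applies four screens to candidate sequences, using
forward hits (candidate → reference proteome) and reverse hits
(candidate → reference), both in the 12-column BLAST `-outfmt 6` layout
parsed by `parse_hit_table()`:

1. **E-value screen** — keep candidates with at least one forward hit
   whose E-value is ≤ the cutoff (default `1e-28`). The comparison is
   inclusive: a hit at exactly the cutoff passes.
2. **Reciprocal-best-hit screen** — in the reverse table, the hit with
   the maximum bit score must land on one of the accepted reference IDs.
   Ties at the maximum are resolved permissively: if *any* top-scoring
   hit is an accepted reference, the candidate passes. A candidate with
   no reverse hits at all fails (absence of evidence is treated as
   failure, not as a pass).
3. **Reference coverage screen** — per candidate/reference pair, the
   subject-side spans of all HSPs are pooled and merged
   (`IRanges::reduce`), and the merged length divided by the reference
   length must be ≥ the threshold (default 0.80, inclusive). Pooling is
   deliberate: a single long HSP and two abutting HSPs that jointly
   cover the same residues are equivalent evidence of full-length
   homology. Coverage is computed on the *subject* (reference) side
   because the question is "how much of the known full-length protein is
   represented", not how much of the candidate aligns.
4. **Folded-region screen** — within a stated reference interval (for
   the worked examples, residues 44–500, the predicted folded portion),
   the total number of *uncovered* reference residues must be ≤ a
   tolerance (default 40). This guards against candidates that reach
   80% coverage by aligning well to disordered termini while missing
   part of the structured core.

Each screen is also exported on its own (`apply_evalue_cutoff()`,
`reciprocal_filter()`, `coverage_filter()`, `folded_region_filter()`),
and `filter_chain()` returns a per-candidate report with one logical
column per screen so rejections are attributable.

```{r filter-example}
fw <- parse_hit_table(system.file("extdata", "toy_forward_hits.tsv",
                                  package = "nrbpfam"))
rv <- parse_hit_table(system.file("extdata", "toy_reverse_hits.tsv",
                                  package = "nrbpfam"))
cfg <- filter_config(evalue_cutoff = 1e-28, min_reference_coverage = 0.80,
                     folded_region = c(44, 500), folded_tolerance = 40,
                     accepted_reference_ids = c("REF1", "REF2"))
res <- filter_chain(fw, rv, cfg, c(REF1 = 500, REF2 = 480))
res$report
```

The bundled toy tables place one candidate on each side of every
boundary (E-value exactly at the cutoff, coverage 0.798 vs 0.854,
uncovered folded residues 40 vs 41), so the fixture doubles as a
boundary-semantics specification.

# Pseudokinase triad classification

A kinase is called a *pseudokinase* here from the state of the three
catalytic residues: the β3-strand lysine, the HRD aspartate and the DFG
aspartate. `build_profile()` turns a trusted seed alignment of intact
kinase domains into a position-specific scoring model:

* per-column amino-acid frequencies with a Laplace pseudocount of 1,
* log~2~-odds scores against a uniform 1/20 background,
* columns that are more than 50% gap are treated as inserts and dropped,
  with the triad column indices remapped accordingly (a profile whose
  triad columns are themselves dropped is rejected as unusable).

`align_to_profile()` aligns a query to the profile with a global
affine-gap three-state dynamic program (match/delete/insert; switching
between delete and insert re-opens a gap). This step is implemented in
compiled code because no installed package exposes profile-to-sequence
alignment as a reusable primitive; its scores are verified in the test
suite against brute-force enumeration of all global alignments on small
instances. Alignment is *global* by design: the seed alignment spans
the kinase domain only, and the query is expected to be a comparable
domain-scale sequence, so local alignment could silently skip a
degenerate triad position.

`call_triad()` reads the query residues mapped to the three triad
columns — a residue aligned to a gap counts as a mismatch — and
`classify_pseudokinase()` applies the decision rule: **pseudokinase if
and only if at least 2 of the 3 triad residues deviate** from the
K/D/D consensus. The 2-of-3 rule tolerates a single lineage-specific
substitution at one site, which occurs in bona fide active kinases,
while requiring concerted degeneration for a pseudokinase call.

```{r triad-example}
seed_cfg <- family_sim_config(
  4, seq_length = 100, base_rate = 0.03,
  triad_state_per_clade = c(invertebrate = "intact", P1 = "intact",
                            P2 = "intact"),
  seed = 7)
seed_sim <- simulate_family(seed_cfg)
profile <- build_profile(seed_sim$sequences, seed_sim$triad_positions)
fam <- simulate_family(family_sim_config(4, seq_length = 100, seed = 7))
classify_sequences(fam$sequences, profile)[1:4, ]
```

# Alignment masking and pairwise identity

`mask_alignment()` keeps a column if and only if its gap fraction is
*strictly below* the threshold (default 0.10): a column with exactly
10% gaps is removed. `pairwise_identity()` wraps a Biostrings global
alignment (BLOSUM62, gap open 10 / extend 0.5 by default) and reports
percent identity; positions where either row is a gap are never counted
as identical. Three denominator conventions are selectable because
published identity figures are not comparable otherwise: `"alnlen"`
(all alignment columns, the default and the convention behind the
family's headline 55.7% NRBP1-vs-NRBP2 figure), `"shorter"` (length of
the shorter sequence), and `"cols"` (columns with no gap in either
row).

# Divergence statistics

`leaf_root_distances()` sums branch lengths from each tip to the root
(`ape::node.depth.edgelength`); `root_at_outgroup()` reroots on an
outgroup tip, splitting its pendant branch 50/50 — the even split is
arbitrary but stated, and leaf-to-root *differences between clades* are
unaffected by where along that branch the root is placed, only the
outgroup's own distance is. `compare_clade_distances()` runs a Welch
(unequal-variance) two-sample *t*-test per requested clade pair and
adjusts across pairs with Benjamini–Hochberg. Degenerate inputs use
fixed conventions rather than `NaN`: two clades with identical constant
values give *t* = 0, *p* = 1; constant but different values give
*t* = ±Inf with the smallest representable *p*; both cases are flagged
in a `degenerate` column. Clades with fewer than two assigned leaves
are an error, not a silent skip. `paired_score_test()` is the matching
one-sample *t* on per-query score differences (e.g. paired bit scores
against two references), also reporting the fraction of queries
favoring the first reference.

# Quantification

For RIP-qPCR, `rip_fold_enrichment()` computes, per fraction,
ΔCt = Ct(RIP) − [Ct(Input) − log~2~(dilution factor)] — the input is
diluted before qPCR, so its Ct is first corrected back to the undiluted
scale — then ΔΔCt = ΔCt(experimental) − ΔCt(control) and fold
enrichment 2^−ΔΔCt^. When the two IPs pull down unequal protein
amounts, the fold is *divided* by the IP protein ratio
(experimental/control) by default: enrichment attributable to more
captured protein is discounted. The opposite convention exists in the
literature, so `direction = "multiply"` is selectable and the choice is
echoed in the result. `ddct_expression()` is standard 2^−ΔΔCt^ relative
expression against a reference target, normalized to the mean ΔCt of
the control group. `retro_activity()` is the ratio of
retrotransposition-reporter colonies to transfection-control colonies,
optionally renormalized to a named condition.

```{r quant-example}
ct <- simulate_ct_table(true_fold = 8, dilution_factor = 10, noise_sd = 0)
rip_fold_enrichment(ct, ip_protein_ratio = 2)
```

# The synthetic generator: what it does and does not emulate

`simulate_family()` produces a three-clade protein family — an
invertebrate outgroup clade and two vertebrate paralog clades, P1 and
P2 — with known ground truth:

* **Topology and branch lengths.** Each clade is a balanced binary
  subtree. Internal edges are fixed at `base_rate` (default 0.05
  substitutions/site); only the *pendant* (leaf) edges are random,
  drawn i.i.d. Exponential with mean `base_rate`. This makes
  within-clade leaf-to-root distances i.i.d., so the Welch test on
  clade distances is exactly calibrated — under
  `rate_multiplier_fast_clade = 1` the false-positive rate is nominal,
  which the test suite checks empirically. P2's edges are scaled by
  `rate_multiplier_fast_clade` to plant accelerated divergence.
* **Substitution.** Per branch of length *b*, each site independently
  substitutes with probability 1 − e^−b^, uniformly over the 19 other
  residues. This is a Jukes–Cantor-style simplification — no rate
  heterogeneity across sites, no exchangeability structure such as
  BLOSUM/WAG, no indels along the tree (insertions are planted
  separately where tests need them).
* **Triad planting.** Triad positions sit at fixed relative positions
  (20%, 50%, 65% of the sequence length), are held invariant during
  simulation, and are then set per clade to `"intact"` (K/D/D) or
  `"degenerate"` (all three replaced by random non-consensus residues).
  The default is all-degenerate, matching the family under study, in
  which both vertebrate paralogs and the invertebrate ancestor are
  pseudokinases.
* **Seeding.** One user seed expands deterministically into three
  independent sub-streams (tree, sequences, triad), so the same seed
  always reproduces the same family, and families sharing a seed share
  an ancestral sequence. The latter matters: a classification profile
  must be built from a seed family *homologous* to the queries — i.e.
  simulated from the same seed — for alignment to be meaningful, just
  as a real profile must come from the same domain family.

`simulate_hit_tables()` scores each simulated sequence against a
reference set with genuine Smith–Waterman local alignments
(`Biostrings::pairwiseAlignment`) and converts raw scores to bit scores
and E-values with the Karlin–Altschul parameters for BLOSUM62 with gap
costs 11/1 (λ = 0.267, K = 0.041). It emulates search *scoring*, not
search *heuristics*: there is no seeding/extension, no composition
adjustment, and one HSP per pair, so E-values are comparable to BLAST's
in form but not numerically identical to what BLAST would report.

`simulate_ct_table()` inverts the RIP model exactly (optionally with
Gaussian Ct noise), so the analysis side can be tested as a round trip.

Problem sizes used in the package's own validation — 3 × 67 leaves for
classification, 3 × 50 leaves at 300 residues for the divergence power
and level checks, 100 replicate simulations per condition — were chosen
to keep the full test suite within a few minutes while leaving the
statistical checks well-powered; they are package choices, not
properties of the underlying methods.

# Limitations

* The evolutionary model is intentionally minimal (uniform
  substitution, fixed topology shape, no tree-level indels); it
  supports *verification* of the statistics, not realistic sequence
  simulation.
* E-values from the simulator use fixed Karlin–Altschul parameters and
  unpooled single HSPs; absolute values should not be compared against
  real BLAST output.
* The canonical human NRBP1/NRBP2 UniProt sequences are not bundled, so
  `nrbp1_nrbp2_identity()` requires a user-supplied FASTA; everything
  else in the package runs fully offline.
* `compare_clade_distances()` treats leaf-to-root distances as
  independent observations. On real (non-simulated) phylogenies shared
  internal branches induce correlation, so its *p*-values there are
  approximate; the generator is designed so that this assumption holds
  exactly in validation.
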