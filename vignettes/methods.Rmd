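---
title: "Hallmark-gene-guided viral lineage mining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hallmark-gene-guided viral lineage mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the procedure

N4-like viruses (family *Schitoviridae*) are bacteriophages recognizable by
seven universal, single-copy **hallmark genes**: the viral DNA polymerase
(vDNAP), major capsid protein (MCP), portal, tail protein, large and small
terminase subunits (TerL, TerS), and a giant virion-encapsidated RNA
polymerase (vRNAP) of roughly 2,800-3,800 aa that carries the conserved
E-x-D-G-x-x-x-G active-site motif. `schitomine` implements, as reusable and
tested R functions, the reference-guided procedure for discovering and
characterizing members of such a lineage in genome and metagenome
collections:

1. **Orthology** (`cluster_families()`, `classify_families()`): all-vs-all
   protein comparison of the reference genomes, reciprocal-best-hit (RBB)
   orthologous pairs, Markov clustering (MCL, inflation 2) into protein
   families, and flagging of core (presence in ≥ 95% of genomes),
   single-copy, and hallmark (universal + single-copy) families.
2. **Profile mining** (`build_msa()`, `build_profile()`,
   `iterative_search()`): per-family profiles built from member alignments
   and searched iteratively against the candidate ORF database until the
   hit set stops changing.
3. **Screening** (`screen_candidates()`): polymerase candidates shorter
   than 2,500 aa are removed, survivors must contain the E-x-D-G-x-x-x-G
   motif, candidate genomes are deduplicated at 99% global nucleotide
   identity, and each contig is classified by hallmark completeness —
   high-quality (HQ) iff all seven types are present exactly once,
   chimera-flagged if any type is multi-copy, otherwise *k*-core.
4. **Proviruses and hosts** (`detect_proviral_region()`,
   `match_spacers()`): host contigs over 100 kbp are segmented by a
   maximal-scoring-run rule over per-gene viral/host labels, and hosts are
   predicted by exact (100% identity, 100% coverage) CRISPR-spacer
   matching on both strands.
5. **Taxonomy and pangenome** (`intergenomic_similarity()`,
   `cluster_ranks()`, `content_network()`, `accumulation_curve()`):
   BLASTN-based intergenomic similarity normalized by the total length of
   both genomes; single-linkage rank clustering at 95 / 70 / 20% for
   species / genus / subfamily; a gene-sharing network with hypergeometric
   edge significance; and protein-family accumulation curves with 300
   resamples per point.
6. **Co-phylogeny and covariance** (`srfv()`, `mfdca()`,
   `covariance_call()`): strict Robinson-Foulds values between hallmark
   trees, and mean-field direct coupling analysis of genome-paired
   alignments with the top-1% rule and control-based calling.
7. **Annotation** (`annotate_profiles()`, `amg_tally()`): best-hit
   annotation against a labeled profile library at E ≤ 1e-5 and the
   habitat-normalized auxiliary-metabolic-gene (AMG) tally (detections per
   genome per group, reported at two decimals).

`run_pipeline()` composes the stages in this order and writes per-stage
tables plus manifests (parameters, seed, input/output digests) so every
summary number is traceable to a file.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| search E-value | 1e-10 | expectation | recruitment threshold for orthology and profile mining |
| query cover | 0.5 | fraction | minimum aligned fraction of the query in all-vs-all search |
| MCL inflation | 2 | — | granularity of family clustering |
| core fraction | 0.95 | fraction | "nearly 95%" core-genome rule, applied as ≥ `ceil(0.95 n)` genomes |
| polymerase length floor | 2,500 | aa | separates the giant vRNAP (2,842-3,820 aa in references) from T7-like polymerases |
| motif | `ExDGxxxG` | — | vRNAP active-site screen (`x` = any residue) |
| dedup identity | 0.99 | fraction | global-mode duplicate removal of candidate genomes |
| host length floor | 100,000 | bp | "over 100 kbp" host-contig rule (strict) |
| spacer rule | 100/100 | % | exact full-length spacer matching |
| rank thresholds | 95 / 70 / 20 | % similarity | species / genus / subfamily |
| accumulation resamples | 300 | — | per-point resampling of the accumulation curve |
| DCA pseudocount | 0.5 | M_eff units | frequency regularization |
| DCA reweighting | 0.8 | identity | sequence redundancy cutoff |
| top fraction | 0.01 | — | covariance selection rule |
| annotation E-value | 1e-5 | expectation | functional annotation threshold |

## Profile architecture and E-value calibration

Profiles are calibrated position-specific scoring models rather than full
hidden Markov models: match states are alignment columns with at most 50%
gaps; per-column frequencies receive background-proportional pseudocounts;
scores are log2 odds against the background (uniform by default — the
background composition of the real families is not part of the model and
is configurable); local alignment uses affine gap penalties of 4.0 / 0.5
bits. Statistical significance is calibrated per profile by scoring 1,000
shuffled decoys (residues resampled from the training alignment) and
fitting a Gumbel law by moments; E-values are length-corrected relative to
the calibration length and scaled by the database size. The same decoy
scheme calibrates the sequence-sequence search, with the Gumbel location
regressed on `log(m n)`. An import hook (`read_hits_tsv()`,
`read_alignment()`) accepts externally computed HMM-search tables and
alignments wherever profiles or alignments are consumed.

The iterative search treats the recruited hit-identifier set as its state
and stops at the strictest checkable criterion — set equality between
iterations. Hits are accumulated as a union across iterations, making
recruitment monotone by construction; newly recruited members enter the
alignment by profile-guided insertion (insertions relative to the profile
are discarded), with full realignment available via `realign = TRUE`.

## The synthetic community

`generate_community()` is first-class, tested code that defines the study
conditions for validation. It emulates: a reference set of complete
genomes sharing the seven hallmark families at a controlled within-family
identity (default 0.85, substituted at an exact per-sequence count so
realized identity never falls below the setting); metagenome contigs
carrying 1..7 hallmark types, always anchored on the polymerase (the
mining anchor); decoy contigs with a polymerase related at ~65% identity
but scrubbed of the motif; chimeric contigs with duplicated hallmark
copies; host contigs > 100 kbp composed of unrelated host genes with one
complete donor genome inserted verbatim at a recorded 0-based half-open
interval; and 32-nt CRISPR spacers copied (on either strand) from
complete viral genomes with host-taxon labels. About a quarter of the
reference isolates are temperate — they carry an integrase + DGR
integration module, as real isolate collections do — and every provirus
donor carries it. Gene realization uses one fixed codon per amino acid so
that ORF extraction recovers planted genes exactly (leucine and serine
use TTA/TCA, whose reverse complements are stops, keeping reverse-strand
mirror ORFs rare), and each output class draws from its own seeded RNG stream so
that enabling one class never perturbs another — identical configurations
are byte-identical.

Default problem sizes — 10 reference genomes, 12 metagenome contigs (three
of them complete), 3 decoys, 2 chimeras, 2 host contigs of 120 kbp, a
2,850-aa polymerase — were chosen once as a desk-scale community that
preserves every structural constraint of the real system (polymerase
length above the 2,500-aa filter and within the reference range, host
contigs above the 100-kbp rule, seven single-copy hallmarks).

What the generator does **not** emulate: tree-shaped evolution (members
are independent draws around a consensus, so phylogenies are star-like),
realistic intergenic architecture or operon structure, codon usage,
read-level sequencing error, and assembly artifacts other than the two
modeled classes (duplicated hallmarks, embedded proviruses). Passing
tests therefore demonstrate the correctness of the procedures under the
stated statistical structure, not performance on real metagenomes.

## Numerical choices

- **ORF model**: ATG-only starts, standard genetic code, six frames,
  coordinates 0-based half-open including the stop codon. By default one
  ORF per (frame, stop) locus is reported — the outermost ATG — because
  nested sub-ORFs of a single locus would inflate hallmark copy counts
  and falsely flag every genome as chimeric; `longest_only = FALSE` gives
  the literal all-ORFs behavior, and both are tested against an
  exhaustive frame-scan oracle.
- **MCL**: self-loops equal to each node's maximum incident weight
  (floor 1, so weakly connected pairs are not atomized), column
  normalization, expansion by squaring,
  elementwise inflation, convergence when the matrix changes by < 1e-6
  (sup norm) or 200 iterations; clusters are read off attractor rows and
  overlapping attractor systems merged. Deterministic throughout; RBB
  best-hit ties break by bitscore then lexicographic subject id.
- **Dedup**: greedy incremental clustering by decreasing length (ties:
  lexicographic id); global identity = matches / global alignment length
  with end gaps penalized. Two conservative screens (a length-ratio bound
  and a worst-case shared-15-mer bound) skip only pairs whose identity is
  provably below the threshold, so the greedy result is unchanged.
- **Proviral segmentation**: overlapping ORF calls are first resolved to
  loci (viral-scored genes always kept; non-viral ORFs admitted
  longest-first while overlapping kept calls by at most half their own
  length — a reverse-strand mirror of a gene is not independent host
  evidence); genes then score +1 (viral profile hit at E ≤ 1e-5) or −1
  (host penalty, configurable), and all maximal non-overlapping
  positive-sum runs (iterated best-segment extraction over prefix sums,
  ties toward the smallest start) become candidate regions, trimmed to
  the outermost viral gene and required to contain a hallmark hit. `--import-checkv`-style external region tables can be
  substituted upstream of the host-prediction stage.
- **Intergenomic similarity**: BLASTN (word 7, reward 2, penalty −3, gap
  5/2, dust off); overlapping aligned blocks on the same genome are
  merged before identical bases are counted (preventing repeated regions
  from pushing similarity above 100%), and the count is normalized by the
  total length of both genomes. Identity contributions of overlapping
  HSPs are discounted by the overlapped fraction, processing HSPs in
  bitscore order.
- **Rank clustering**: single linkage. The published subfamily boundaries
  were drawn as a minimally conservative reading of a similarity heatmap,
  and single linkage reproduces exactly that reading — known borderline
  subfamily merges are reproduced rather than patched. Nesting is
  enforced by construction (genus components computed within subfamily
  components, species within genus), so the species ⊂ genus ⊂ subfamily
  invariant holds for any threshold triple.
- **sRFV**: both trees are pruned to shared leaves; the symmetric
  difference of non-trivial bipartitions is normalized by the total
  split count of the two trees, which equals the classic 2(n−3) for
  fully resolved trees and degrades gracefully for multifurcations. Tree
  construction is neighbor joining on alignment mismatch distances
  (negative branch lengths clamped to 0); maximum-likelihood trees can be
  imported as Newick for full fidelity.
- **mfDCA**: gaps (and unknown residues) are the gauged-out 21st state;
  sequence weights 1/n at 0.8 identity; pseudocount 0.5·M_eff; couplings
  from −C⁻¹ over 20 states per column (ridge 1e-8 with a warning if C is
  singular); the two-site direct distribution's compatibility fields are
  fitted by sequential iterative proportional scaling, converged when the
  normalized field vectors change by less than 1e-6 between sweeps (at
  most 10,000 iterations — the sequential scheme reaches this even for
  near-deterministic couplings, where the plain simultaneous update
  oscillates). DI is clamped at 0 against
  floating-point underflow. The Welch (unequal-variance) two-sided t-test
  backs the covariance verdict.
- **Degenerate inputs**: empty hit tables, empty spacer sets, single-row
  alignments (allowed as seeds), all-gap alignments (error), asymmetric
  matrices (error beyond 1e-9), non-IUPAC contig characters (error), and
  spacers with degenerate bases (skipped with a warning) are all handled
  explicitly and tested.

## Design decisions

- The seven-hallmark rule, motif screen, and 2,500-aa filter apply to the
  polymerase family only; no length sanity check is applied to other
  hallmark hits (none is part of the procedure).
- Chimera-flagged contigs are excluded from the HQ set but retained in
  all reports — they are discussed artifacts, not silently dropped
  records.
- The content-network edge weight, `-log10` of the hypergeometric tail
  probability of the shared family count, replaces an external clustering
  tool's unstated significance score; the edge cutoff (weight ≥ 1,
  P ≤ 0.1) is configurable.
- The annotation stage takes any labeled, calibrated profile library; the
  synthetic library shipped for tests is built from the generator's
  accessory-family truth, and `read_annotations_tsv()` imports external
  per-protein annotation tables (e.g. a study's supplementary tables) for
  the same tally. AMG class labels are carried from library metadata,
  never recomputed.
- Both family entry points are exposed: RBB+MCL families from the
  reference set (`cluster_families()`), and gene-content MCL clusters of
  genomes (`content_network()`); the procedure uses the former for
  core-genome definitions and the latter for genome grouping.
- Where one alignment contains a genome twice, `pair_msa()` keeps the
  first row and warns; multi-mapping spacers are all reported, ranked by
  match count.

## Problem sizes and runtime

The shipped validation exercises the full pipeline on the default
community (10 + 17 contigs + 2 hosts, ~330 kb of sequence, ~1,300 ORFs),
which completes in about 2-3 minutes on one CPU; the covariance
validation uses 20 paired alignments of 500 rows × 24 columns plus a
1,000-row null, under a second each. These sizes are the package's
validation design: large enough to exercise every rule (partial
completeness classes, duplicated hallmarks, motif-free decoys, embedded
proviruses, reverse-strand spacers), small enough to be re-run routinely.

## Known limitations

- E-values come from a moment-fitted Gumbel on shuffled decoys; they are
  well-calibrated for ranking and thresholding at the decoy scale but are
  not exchangeable with a specific external tool's E-values.
- The progressive aligner is a guide-tree Needleman-Wunsch without
  iterative refinement; highly gapped families will align worse than with
  a production aligner — importing an external alignment is the fidelity
  path.
- Neighbor joining on mismatch distances stands in for maximum-likelihood
  tree inference; support values are not computed.
- Rank clustering at 95/70/20% uses the same similarity for all three
  ranks; whether the subfamily threshold should use a different identity
  definition is left to the caller (the similarity function is the
  documented, literal normalization).
- The habitat-normalized AMG tally reproduces the report semantics
  (detections per genome per group); reproducing a specific published
  table additionally requires that study's per-protein annotation inputs
  via the import hook.
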