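---
title: "Methods: palindrome discovery and sequence-class annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: palindrome discovery and sequence-class annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palindromekit)
```

# Scope

`palindromekit` annotates the repeat-rich architecture of sex chromosomes:
it discovers palindromes (long, near-identical inverted repeats), groups
homologous palindromes within and across species, partitions a chromosome
into pseudoautosomal (PAR), satellite (SAT), ampliconic (AMP) and ancestral
(ANC) sequence classes, applies the standard post-filter to
segmental-duplication calls, and calls multi-copy and ampliconic gene
families from protein sequences.  A synthetic-chromosome generator with
machine-readable planted truth exercises the whole pipeline end to end.

All coordinates everywhere in the package are 0-based half-open
(`[start, end)`, the BED convention); 1-based input is accepted nowhere
except through explicitly converted files.

# Palindrome model and calling thresholds

A palindrome is a pair of arms on one chromosome in inverted orientation,
optionally separated by a spacer.  A candidate is called a palindrome iff

* each arm is at least `min_arm_len_bp` = 8,000 bp long,
* the arms align (arm1 against the reverse complement of arm2) at
  `min_arm_identity_pct` >= 98% identity,
* the spacer (`arm1.end` to `arm2.start`) is at most `max_spacer_bp` =
  500,000 bp, and
* less than `max_repeat_fraction` = 80% of the candidate footprint is
  covered by annotated repeats.

Interpretation choices the thresholds leave open, and how this package
resolves them:

* "length" applies to **each arm**, not the total span: the definition of
  the feature is inverted repeats of a minimum arm size.
* The repetitive-content footprint is the **full span** (both arms plus
  spacer) by default; `palindrome_thresholds(repeat_scope = "arms")`
  switches to arms only.  "Candidate" most plausibly refers to the whole
  feature.
* The spacer constraint is measured `arm1.end` to `arm2.start` (not centre
  to centre).
* Arm identity is computed from a **global** alignment over the candidate
  arm intervals, with identity = matches / alignment columns and gap
  percentage = gap columns / alignment columns (gap opens and extensions
  both count as columns).  This matches the common "identity/continuity"
  convention of chained-alignment tools and makes the 85%/5% filter below
  well defined.

Overlapping and nested calls are all reported, since real palindrome
architecture is frequently nested; `non_redundant = TRUE` keeps the longest
call per overlap group.

# Discovery algorithm

The discovery step is a seed–chain–extend self-alignment:

1. Exact k-mer seeds (default `k = 21`) are matched between the chromosome
   and its reverse complement.  Soft-masked (lowercase) bases and bases
   covered by the supplied repeat track never seed, but are aligned through
   during extension — standard practice for masked assemblies.  k-mers
   occurring more than `max_kmer_occ` = 64 times are skipped (repeat
   damping).
2. Seeds collinear in inverted orientation lie on a common anti-diagonal;
   they are chained when within `band_width` = 200 bp of diagonal drift and
   at most `max_seed_gap` = 5,000 bp apart.
3. Overlapping candidates are resolved greedily by chain support
   (most seeds wins; ties break to the leftmost), then each surviving arm
   pair is scored with a banded global alignment (linear gap cost; scores
   `match = 1`, `mismatch = -2`, `gap = -3`).

With these defaults, a chance seed between a 2-Mb chromosome and its
reverse complement occurs about once (2e6^2 / 4^21), so spurious chains of
palindrome-arm length are effectively impossible, while arms diverged a few
percent carry seeds every few tens of bases.  Boundary error against
planted truth is a few bp — far inside the ±100-bp tolerance used by the
recovery checks.  At 21-mer seeding the detectable arm divergence extends
comfortably past the 2% the 98% identity threshold implies.

Users with externally computed alignments can skip internal discovery
entirely: `read_alignment_table()` imports generic TSV or PAF-like records
with identity, gap, matched-base and coverage fields.

# Homologous palindrome clustering

Arm-to-arm alignments (within and across species, both orientations) are
filtered with the standard discard rules: identity < 85%, gaps > 5%,
< 500 matched bases, or < 40% coverage of either arm.  The rules are strict
inequalities, so boundary values (exactly 85/5/500/40) are kept.  One
filter serves orthologous and paralogous links alike, so clusters may mix
the two.  A single surviving alignment suffices for a link (no reciprocity
requirement).  Clusters are the transitive closure (connected components)
of the link graph, computed by union–find; cluster ids are the
lexicographically smallest member.  `sharing_summary()` counts clusters
whose species set contains each named species group, and tabulates exact
species combinations.

# Sequence classes

The annotation workflow is sequential:

1. **PAR**: maximal chromosome-terminal blocks where X and Y align in
   direct orientation.  The field describes this step only as
   "aligning X and Y", leaving parameters open; the package requires >= 99% identity over a
   terminal block of >= 50 kb, bridging interruptions up to 10 kb, with
   identity verified by 2-kb banded alignments sampled across the block
   (aligning multi-megabase blocks end-to-end would cost quadratic band
   area for no additional decision power).  A block at the opposite
   terminus is PAR2.
2. **SAT**: repeat annotations merged when within 1 kb (inclusive), merged
   spans strictly greater than 0.25 Mb emitted.
3. **AMP**: the union of palindrome footprints (full spans including
   spacers by default, switchable) and high intrachromosomal-similarity
   intervals: 5-kb windows of the repeat-masked chromosome whose best
   non-self locus aligns at >= 50% identity, in maximal runs spanning
   strictly more than 90 kb.  Candidate loci come from co-diagonal 11-mer
   seed clusters (at least `min_seeds = 10` seeds); as with word-hit-seeded
   BLAST searches, exact seeding bounds sensitivity, so copies below
   roughly 70% identity are not proposed — inverted copies enter AMP
   through the palindrome union instead, and only direct-orientation
   copies are scanned here.
4. **ANC**: everything else.  On the Y, remaining ANC subregions
   overlapping a gene annotated as belonging to an ampliconic family are
   reassigned AMP; genes of ancestral families confirm ANC.  The
   refinement only assigns remaining subregions — it never demotes AMP
   candidates lacking genes.

When classes overlap, precedence is **PAR > SAT > AMP > ANC**: the workflow
is sequential (PARs and satellites are fixed first), and a segment nested
in two matching classes takes the higher-precedence one.  The result is
validated as an exact tiling of `[0, chrom_length)` — zero gap and zero
overlap bases — on every call.

Segmental-duplication records (from any discovery tool) are post-filtered
with `filter_segdups()`: identity > 90%, length > 1 kb, satellite content
< 70%, all strict.

# Gene families

All-vs-all best local alignments (affine-gap Smith–Waterman under BLOSUM62,
gap open 10, extend 1) define homology edges at >= 50% identity over
>= 35% of **both** protein lengths ("35% of protein lengths", plural, is
read as both; coverage of only the shorter protein would link short
domain matches).  Identity is matches / alignment columns of the single
best local alignment.  Families are single-linkage components with at
least two members; components with no within-species edge are removed (the
refinement step).  A family is **ampliconic** iff some within-species pair
reaches 97% protein identity — a cross-species pair at 99% does not
qualify.  Gene density per sequence class assigns each gene by its
midpoint (avoiding double counting at class boundaries) and the
goodness-of-fit test is the Pearson chi-squared against length-proportional
expectations with Bonferroni adjustment.

# Statistics kernel

The t test is the Welch unequal-variance form (group variances of GC
samples are not guaranteed equal; the pooled form is a special case the
data rarely earn).  When both samples are constant and equal the
convention statistic 0, one-sided p 0.5 is returned with a warning.  The
Wilcoxon rank-sum test uses midranks for ties; p is exact (null rank-sum
distribution) when the combined sample size is at most 40 and there are no
ties, otherwise the normal approximation with continuity and tie
corrections.  Both match the base-R reference implementations to 1e-9 on
fixed vectors, and the exact path equals exhaustive permutation
enumeration at n1 = n2 = 5; their empirical type-I error at alpha = 0.05
is calibrated over 10,000 null replicates.  Bonferroni adjustment is
`min(1, p * m)`.

# Synthetic data: what it emulates, and what it does not

`synth_chromosome()` plants palindromes (arm2 = mutated reverse complement
of arm1), tandem satellite arrays (recorded in the repeat track),
dispersed duplications, shared PAR blocks on X/Y pairs, and gene
annotations, over a uniform-composition random background.  The mutation
model is independent per-base substitution to a uniformly chosen different
base, plus optional geometric indels (mean 2 bp) — the simplest model that
exercises the identity thresholds.  Identical spec + seed reproduce
byte-identical FASTA/BED/TSV output.

`synth_protein_families()` plants families on two-level trees (species
ancestors, then copies) with substitution counts fixed to
`round(divergence × length)` at interior positions; the first and last 10
residues are conserved, emulating conserved terminal domains and keeping
best local alignments full length, so realized pairwise identities land
within ±2 points of the request for 200-residue proteins.  Requesting
cross-species identity above within-species identity on the two-level tree
is infeasible and raises an error; asymmetric structures (e.g. a family
whose only near-identical pair is cross-species) are specified with
explicit per-member divergences instead.

What the generator does **not** emulate: transposable-element landscapes,
tandemly structured amplicon internal repeats, gene conversion between
arms, GC heterogeneity, centromeres, or assembly error.  Passing the
planted-truth checks therefore demonstrates that the algorithms implement
their stated rules correctly at realistic scales — not that the thresholds
themselves are optimal for any particular genome.

# Problem sizes used in the checks

The recovery checks run on 2-Mb chromosomes (20 seeds; three qualifying
palindromes and three single-violation decoys each), window mapping on
1-Mb chromosomes (planted 120-kb and 60-kb duplications; 20 unique-sequence
seeds), PAR detection on 1.2–4-Mb pairs with planted 2.5-Mb PAR1 and
95-kb PAR2, class assignment on 100 random interval layouts with a
per-base oracle, protein families on 20 seeds of a three-species design
checked against a full dynamic-programming oracle, and the statistics
kernel on 10,000 null replicates.  These sizes keep the full suite
comfortably within a few minutes on one CPU while leaving every threshold
decisively exercised.

# Known limitations

* Window-mapping sensitivity is seed-bounded (see above); the 50% identity
  parameter is honoured for proposed candidates, but candidates far below
  ~70% identity are not proposed.
* `align_pair()` is a banded global aligner; arms whose true alignment
  wanders outside the band (large unbalanced indels) will be scored
  conservatively.  The band is a parameter.
* Arm-alignment coverage percentages from the internal (global) aligner
  are always 100; the 40% coverage rule mainly bites on imported local
  alignments.
* PAR detection assumes PARs are chromosome-terminal, as they are in the
  chromosomes this package targets.

```{r example, eval = FALSE}
# a minimal end-to-end run
spec <- synth_spec(chrom = "chrT", length = 2e5, features = list(
  feat_palindrome(50000, 10000, 5000, divergence = 0.005)))
chr <- synth_chromosome(spec, seed = 7)
detect_palindromes(chr$seq, chr$repeats)
```
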