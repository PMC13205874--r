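---
title: "Methods: comparing the haplotypes of a phased diploid assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the haplotypes of a phased diploid assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A haplotype-resolved (phased) assembly of a heterozygous diploid gives
both parental chromosome copies as separate sequences. The two
haplotypes of an outcrossing plant can differ by millions of SNPs,
hundreds of thousands of insertions and deletions, large inversions and
translocations, highly diverged regions (HDRs) where the copies still
align but poorly, and sequence present in one haplotype only. These
differences have gene-level consequences: *hemizygous* genes exist on
one haplotype with no homologous copy at the corresponding locus of the
other, and even gene pairs with byte-identical coding sequence can be
expressed differently because their *cis*-regulatory surroundings
diverged.

`hapcompare` implements that analysis chain as a reusable, tested
pipeline: region partition of the two haplotypes, hemizygous gene
detection and categorization, identical one-to-one homolog pairing,
inter-haplotype differential expression (DE) across tissues, promoter
variant burden of DE versus non-DE pairs, and basic assembly QC
(telomere arrays, genetic-map concordance). A phased-diploid simulator
with a complete planted truth set ships as first-class, tested code, so
every stage can be validated end to end.

# Region partition

## Anchors and chains

The comparison is anchor-based. An **anchor** is a k-mer (default
`k = 31`, odd so that no k-mer equals its own reverse complement) that
occurs exactly once in each genome under strand-canonical counting, and
contains no N. Requiring genome-wide uniqueness in *both* assemblies
trades sensitivity inside repeats for zero-ambiguity chaining — a
deliberate choice for genomes whose repeat fraction approaches half the
assembly, where multi-mapping anchors would poison the chains.

Anchors are chained greedily in reference order; a chain breaks when the
reference or query chromosome changes, orientation flips, query
monotonicity fails, or the inter-anchor gap exceeds `max_gap` (default
20 kb, comfortably larger than the indels the caller should bridge but
smaller than chromosome-scale rearrangements). Chains with fewer than
`min_chain_anchors = 3` anchors are noise and are dropped.

## Backbone and rearrangements

Per chromosome, the query partner is the chromosome receiving the most
forward-chain anchors, and the **syntenic backbone** is the maximum-
weight strictly increasing subsequence of forward chains (weight =
anchor count). Reverse chains against the partner are inversions;
chains to another chromosome, or displaced by more than
`trans_displacement = 100` kb, are translocations.

Backbone anchor runs (split wherever consecutive anchors sit more than
`prune_gap = 200` bp apart on either genome) are pruned before gap
analysis when they are *sparse*: in clean sequence anchors step by one,
so a genuine run spans close to its anchor count even when SNPs
interrupt it, while chance intact k-mers inside an HDR spread a few
anchors over hundreds of bases. A run is dropped when its span exceeds
eight times its anchor count (floored at `min_run_anchors = 5`). The
density criterion matters: a populousness-only rule either keeps sparse
HDR survivors (which shatter one diverged region into fragments
separated by 31-bp slivers of "synteny") or, tightened, throws away
legitimately SNP-dense stretches such as the promoter windows where
variants cluster. As a second line of defence, an equal-length residual
whose mismatch density reaches 25 % — two orders of magnitude above any
realistic SNP clustering, and characteristic of HDR interiors — is
emitted as an HDR fragment rather than a run of SNP calls.

## Gap classification

Between consecutive backbone anchors the two gap sequences are trimmed
of their common prefix and suffix, leaving residuals of length `a`
(reference) and `b` (query):

* `a = b = 0` — pure synteny, absorbed into the running SYN block;
* `a = 0` — an insertion (sequence the query haplotype carries extra);
  `b = 0` — a deletion; `min_sv_len` (default 50 bp) is the conventional
  floor for calling these *structural*, but shorter residuals are still
  emitted as small indels so that the partition stays exact;
* `a = b` — equal-length divergence: if at least `hdr_min_len = 500` bp
  and banded-alignment identity is below `hdr_max_identity = 0.9`, an
  HDR; otherwise each mismatching position is a SNP call (ties at the
  identity threshold resolve toward synteny, the conservative side);
* `a != b`, both large — HDR by the same identity rule, with the band
  sized `2|a-b| + 50` so the length difference is always representable;
* `a != b`, both small — emitted as a paired small deletion plus small
  insertion anchored at the same junction.

Inversion and translocation chains are *islands* inside backbone gaps.
Chain ends can overhang neighbouring anchors by up to one k-mer, so each
island side is clipped to the gap that claims it; with breakpoints
accurate to within `k` bp this keeps the partition single-coverage
without losing precision beyond the anchor length. Sequence beyond the
outermost backbone anchors — chromosome ends, including
haplotype-unique terminal segments — is NOTAL (unaligned, i.e.
haplotype-specific).

The invariant that makes all of this testable: the full call set covers
every non-N base of both haplotypes exactly once.
`region_partition_check()` asserts it mechanically, and the test suite
requires zero defects across five independently simulated genomes.

# Hemizygous genes

A gene is **homozygous** iff some gene on the other haplotype lies
within the syntenic projection of its locus *and* has global CDS
identity at or above `cds_identity_threshold = 0.9`; otherwise it is
hemizygous. Projection goes through the two-sided calls (SYN, HDR, INV)
nearest the locus; the partner search window adds
`search_window = 5000` bp on each side. Restricting the search to the
projected window — rather than a genome-wide best hit — prevents
paralogs elsewhere from rescuing a truly hemizygous gene.

CDS identity is `1 - edit_distance / max(length)`: exact equality
short-circuits to 1, equal lengths use the Hamming distance (exact for
the substitution-only divergence that dominates between haplotypes),
and unequal lengths use a banded global edit distance whose band covers
the length difference. A truncated band can only underestimate
identity, which errs toward calling hemizygosity — the conservative
direction for this classifier.

Hemizygous genes are then **categorized** by the region class hosting
them: insertion (sequence specific to their own haplotype), HDR, or
haplotype-unique, taking the class with the largest span overlap
provided it reaches `min_overlap = 0.5`, with ties resolved in the
fixed order insertion > HDR > unique. Genes overlapping no qualifying
class are `unassigned` — published category counts for this kind of
analysis fall short of the hemizygous totals by a gene or so, which is
exactly what an escape category absorbs.

# Identical homolog pairs and differential expression

One-to-one homologs are reciprocal best hits by CDS identity within
syntenic windows; genes with no candidate or with tied best candidates
stay unpaired. A pair is **identical** iff the coding sequences are
byte-equal — "100 % identity" is taken literally, which subsumes equal
length and removes any dependence on alignment scoring.

Identical pairs are the universe for the DE analysis: any reproducible
expression difference between two byte-identical transcripts must come
from regulation. Expression is TPM-normalized (per sample:
count / length-in-kb, scaled to sum to 10^6), compared on
log2(TPM + 1) with pseudocount 1 making zero-handling explicit.

For the test itself the package uses limma's moderated t
(`lmFit`/`eBayes`), fitted per tissue across all pairs, with
Benjamini–Hochberg correction over the entire pair × tissue family and
a pair flagged DE iff any tissue reaches `q < alpha` (default 0.05).
This was a genuinely open design point. A plain per-pair Welch test was
implemented first and is retained as the fallback when there are too
few pairs to pool (< 3), but with two or three replicates per tissue
the per-pair variance estimate is so unstable that even four-fold
planted effects rarely clear FDR correction — in the packaged study
conditions it recovered none of twelve planted effects. Pooling
variance across pairs is the standard remedy in expression analysis,
restores the expected operating point (12/12 recovered, zero false
positives, null type-I error within binomial bounds of 0.05 at ~250
tests), and keeps the response, family and flag rule unchanged.

The choice of one explicit multiplicity family — all pairs × all
tissues jointly — avoids any ambiguity about what BH controls.

# Promoter variant burden

Promoters are the `window = 3000` bp immediately upstream of the TSS,
strand-aware and clipped at chromosome bounds. SNP calls are counted by
position; SV calls (INS, DEL, INV, TRANS, HDR) count once per call
overlapping the window by at least one base, with a zero-length
breakpoint (the anchored empty side of an indel) counting when it lies
inside the window. No length weighting: a 3-kb HDR and a 60-bp
insertion each count one SV — the simplest defensible rule, and the one
whose null behaviour is easiest to reason about.

A pair's burden is the **maximum** of its two promoters' totals. The
analysis never privileges one haplotype as "the" reference, and max is
the symmetric aggregate that preserves a one-sided variant cluster.
DE and non-DE identical pairs are compared with a Wilcoxon rank-sum
test.

# QC

`telomere_scan()` counts exact occurrences of the plant telomere motif
`TTTAGGG` and its reverse complement in 10-kb windows; a chromosome end
is positive when its two terminal windows hold at least `min_copies =
10` copies. Exact counting (no degenerate matches) suffices because the
motif cannot overlap itself. `map_concordance()` reports per-chromosome
Spearman rank correlation between genetic (cM) and physical (bp)
marker positions, with midranks on ties and an orientation-corrected
|rho| since stored maps may run in either direction.
`assembly_stats()` counts maximal N-runs per chromosome, the
granularity needed to report gapless chromosomes.

# The simulator

`simulate_diploid()` builds haplotype 1 explicitly and derives
haplotype 2 **only** by applying the edit script
(`apply_edit_script()`), so the truth set is exact by construction
rather than re-measured. Defaults describe the desk-scale study
conditions used throughout the tests and the acceptance script:

* two chromosome pairs, 500-kb bodies, GC 0.44, telomeric
  `(TTTAGGG)x30` arrays at every end;
* SNPs at 0.005 / bp — the order of ~2.9 M SNPs over a ~317 Mb genome;
* 40 insertions + 40 deletions, log-uniform 50–5000 bp (most SVs in
  such comparisons are well under 10 kb); 2 inversions (5–50 kb) and
  one inter-chromosomal cut-and-paste translocation (5–20 kb);
* 6 HDRs of 2–20 kb at 60–80 % identity, substitutions only — keeping
  HDR truth rectangular avoids compound events whose truth coordinates
  would themselves need an aligner;
* 2 haplotype-unique terminal segments per haplotype (3–10 kb), placed
  between chromosome body and telomere, where unaligned sequence
  genuinely accumulates;
* 120 genes per chromosome, 12 % hemizygous, hosted in insertions :
  HDRs : unique segments at roughly 44 : 52 : 4; hemizygous genes get a
  2x expression boost;
* 60 designated identical pairs (their CDS shielded from SNP planting),
  12 of which receive a 4x cis effect on one random haplotype plus ~25
  extra promoter SNPs and one small promoter insertion;
* negative-binomial counts (dispersion 0.1) for leaf, stolon, rhizome
  and root, 3 replicates each; genetic-map markers monotone in cM with
  jittered spacing.

Where the published analysis this emulates does not state a value
(HDR and unique-segment length distributions, expression baselines,
marker densities), the defaults above are the package's own choices of
a realistic regime, fixed once; they are parameters, not claims.

SNPs are planted only in syntenic background — outside SV/HDR/unique
intervals, at least ~100 bp from event breakpoints, and never inside
the shielded CDS of designated identical pairs. This keeps every
truth record rectangular (a SNP is a SNP, an HDR is an HDR) and makes
recovery metrics sharp. Consequences worth knowing: SNP recall is
measured outside HDRs by construction, and non-designated homozygous
pairs can still be identical by chance (their CDS simply drew no SNP) —
the truth table therefore records *realized* identity, computed from
the sequences, not the designation.

What the simulator does **not** emulate: read-level noise (counts are
drawn, not aligned), annotation error, repeat families (the background
is i.i.d. random sequence, so unique k-mers are denser than in a real
repeat-rich genome), compound SVs, and polyploid subgenome structure.
Passing tests therefore demonstrate correctness of the algorithms under
their stated assumptions, not robustness to dirty assemblies.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based inclusive (GFF3/VCF/TSV) happens in exactly one audited
  function pair, tested on first-base / last-base / length-1 / empty
  intervals. An anchored empty interval `[p, p)` is written 1-based as
  `(p+1, p)` and round-trips.
* One RNG stream per simulator stage, each seeded from the master seed,
  so adding a stage never perturbs earlier stages; every stage is
  byte-deterministic under a fixed seed.
* Welch fallback handles the zero-variance tie (p = 1 on equal means,
  0 otherwise) that discrete counts can produce.
* Genes without CDS are skipped (with a count) rather than fabricated;
  multi-isoform genes contribute their longest-CDS mRNA, giving each
  gene exactly one coding sequence for identity pairing.
* Wilcoxon tests skip with a notice below two observations per group;
  TPM of an all-zero sample is all zeros, flagged, never NaN.

# Problem sizes

The default simulated genome is ~1 Mb per haplotype with ~240 genes per
haplotype and ~4000–4500 planted SNPs. The full test suite simulates a
handful of such genomes (five at default scale for the partition
checks, plus smaller configurations for module tests); the acceptance
script runs one default-scale dataset plus one effect-free replicate
for null calibration. These sizes were chosen so that every planted
event class is represented dozens of times while a complete validation
run stays in the minutes range on a laptop.

# Known limitations

* Duplications (the DUP class of general-purpose SV callers) are out of
  scope; duplicated sequence shows up as non-unique k-mers and falls
  out of the anchor set.
* HDR interiors are not base-level aligned; an HDR call carries
  interval coordinates and an identity bound, not an alignment.
* The anchor-uniqueness requirement means breakpoints inside long
  repeats are localized only to the nearest unique flank.
* Hemizygosity calls inherit annotation quality: a gene mis-annotated
  on one haplotype will surface as hemizygous; expression-based rescue
  is deliberately left to the expression module's comparisons rather
  than folded into the caller.
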