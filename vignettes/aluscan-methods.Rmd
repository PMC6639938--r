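---
title: "Alignment-free Alu insertion discovery and genotyping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free Alu insertion discovery and genotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluscan)
```

## The problem

Alu retrotransposons insert into new genomic locations through
target-primed reverse transcription. A new insertion duplicates a short
stretch of the target site (the TSD), carries an intact element 5′ end, and
ends in a polyA tail. Because an insertion either is or is not present at a
locus, every polymorphic Alu defines a biallelic marker; this package
discovers such markers from raw reads and genotypes them without any read
mapping.

Two complementary discovery directions exist. A *REF– element* is present in
a sequenced individual but absent from the reference genome: the only trace
in the data is reads that cross the insertion junction. A *REF+ element* is
present in the reference and possibly absent elsewhere: it can be found by
inspecting the reference alone.

## Signature matching

The 10 bp consensus at the Alu 5′ end, `GGCCGGGCGC`, is extended to the set
of all sequences at Hamming distance ≤ 1 — `3·10 + 1 = 31` members
(`build_signature_set()`). Scanning is implemented as membership of each
10 bp window in this precomputed set (one hash probe per window), which is
exactly equivalent to per-window Hamming comparison; a property test checks
that equivalence against a brute-force scan. Windows containing `N` never
match. Reads and the reference are scanned on both strands: sequencing reads
sample both strands, so minus-strand scanning is required for full
sensitivity (for the reference scan both-strand scanning is the default and
can be disabled).

Tolerating one mismatch keeps old, diverged copies visible while bounding
the false-hit rate at `31/4^10 ≈ 3×10⁻⁵` per window in random sequence. The
approach requires an intact element 5′ end; 5′-truncated insertions are
invisible to it by design.

## REF– discovery

For every signature hit in a read with ≥ 25 bases 5′ of it (on the hit's
strand), the 35-mer *flank(25) + signature(10)* is recorded and counted
exactly (`scan_read_junctions()`). A candidate is called
(`ref_minus_candidates()`) when:

1. the junction count lies in `[min_support, max_support]`
   (defaults **3** and **100**: at the 20–40× coverage this pipeline
   targets, ≥ 3 suppresses junction 35-mers created by sequencing errors,
   and ≤ 100 suppresses repeat-derived artifacts; both are arguments, since
   very low or very high coverage needs different values);
2. the 25 bp flank occurs exactly once in the reference, counting both
   strands (repeated flanks cannot anchor a breakpoint);
3. the 10 reference bases that follow the flank differ from the observed
   signature — if they match, the "insertion" is simply the reference
   allele of an element already present.

The reported breakpoint is the 1-based position of the first reference base
after the flank, i.e. the base before which the element inserts.

The 35/25/10 geometry is trimmed to 32/25/7 only when building genotyping
pairs: 25 flank bases guarantee unique placement in a mammalian genome,
and 7 element bases are the minimum that reliably distinguishes the two
alleles while fitting a 32-bit two-bit-per-base k-mer word.

## The 25-mer location index

`build_kmer_index()` maps every ACGT 25-mer window of the reference, stored
in canonical (strand-min) form, to its occurrences. The pipeline only ever
asks "zero, one, or many?", so occurrence lists are capped (default 4
entries) with the true total retained — this bounds memory on repetitive
genomes without changing any uniqueness answer. Uniqueness is strand-aware:
one forward plus one reverse-complement occurrence means two placements,
hence not unique. For a palindromic k-mer the two strands coincide and `+`
is reported.

## REF+ discovery

Four monotone stages (`discover_ref_plus()`; per-stage counts via
`cascade()`):

1. **Signature scan** of the reference, both strands.
2. **TSD search** (`find_tsd()`): the 5-mer immediately 5′ of the signature
   is sought at each distance `d ∈ [270, 350]` downstream of the signature
   start (inclusive window, nearest match wins), then the duplication is
   extended in both directions to its maximal exact length. The window
   brackets a full-length element (~280–310 bp) plus a short polyA; the
   5-mer seed corresponds to the minimum TSD length of 5 that is still
   unlikely to occur by chance in an 81-position window (`81/4^5 ≈ 0.08`).
   The distance is measured from signature start to the first base of the
   downstream copy; both endpoints are configurable.
3. **Homology**: Smith–Waterman local alignment of the element span
   (signature start to the end of the downstream TSD copy) against an Alu
   consensus library, match +1, mismatch −2, gap open −5, gap extend −2 (a
   gap of length *g* costs `5 + 2g`), converted to bits with the standard
   ungapped Karlin–Altschul parameters for +1/−2 (λ = 1.28, K = 0.46):
   `bits = (1.28·S − ln 0.46)/ln 2`. Candidates are kept above **100 bits**.
   A perfect ~290 bp match scores ≈ 535 bits; 20%-diverged copies still
   clear 100; random 300-mers stay far below (all three checked in tests,
   the raw scores against an independent dynamic-programming oracle).
   This self-contained scorer replaces an external aligner dependency while
   preserving the "> 100 bits" retention semantics.
4. **Outgroup absence** (optional): the junction 32-mer (flank + first 7
   signature bases) is looked up in an outgroup genome on both strands; the
   candidate passes iff absent. This is deliberately coarse — full synteny
   mapping is out of scope — and when no outgroup is supplied the flag is
   `NA` and candidates are retained with a warning.

REF+ output is a candidate list, not a final catalogue: a reference element
monomorphic in one cohort can be polymorphic in another, which is also why
monomorphic REF+ markers are *retained* by the cohort filter below.

## Pair construction and pair-level filters

`build_pairs()` emits, per element, `kmerA` (reference allele) and `kmerB`
(alternative), both 32 bp, sharing the 25 bp flank:

| class | kmerA tail (7 bp) | kmerB tail (7 bp) |
|---|---|---|
| REF– | reference continuation after the flank | first 7 signature bases |
| REF+ | first 7 signature bases (element in reference) | 7 bases after the downstream TSD copy |

`filter_pairs()` applies four set-level criteria (each a property of the
pair set, so the outcome is order-independent, which is property-tested):
duplicate canonical 32-mers across pairs remove all pairs involved;
breakpoints closer than `min_distance` (**32** bp, one k-mer length —
closer pairs overlap each other's k-mers) remove all involved; either
k-mer with GC fraction above `gc_max` (**0.80**; GC-extreme k-mers show
strong coverage bias in short-read data) removes the pair; and `kmerA`
must occur exactly once in the reference with `kmerB` absent, verified by
direct scan. The distance and GC thresholds are judgement calls — nothing
in the underlying method fixes them — and are therefore arguments.

## Genotyping model

Counts `(n_A, n_B)` of the two 32-mers in the read stream (canonical
matching, exact multiplicity) are modelled as independent Poisson draws.
With λ the expected per-element k-mer coverage and ε the leak rate of an
absent allele (sequencing error plus cross-mapping), the genotype
hypotheses have intensities

- diploid: AA (λ, ε), AB (λ/2, λ/2), BB (ε, λ)
- haploid: A (λ, ε), B (ε, λ)

with a flat prior; the maximum-posterior genotype is called iff its
posterior reaches `min_posterior` (**0.95**; between the degenerate bounds
0.5 and 1, high enough that the (0,0) no-information case — posterior ≈ 1/3
each — is never called). Calibration (`calibrate_caller()`) uses the median
of `n_A + n_B` over informative pairs: for a diploid the two alleles
together always represent two haploid copies, so the total is
genotype-independent and the median is robust to the minority of
misbehaving pairs; `ε = max(0.01·λ, 0.1)`. This replaces an
external-database-driven empirical-Bayes calibration with a self-contained
one; with at least ~100 informative pairs the median is stable, and below
that the user supplies an expected coverage.

The caller is exactly symmetric under allele relabelling (tested), and on
simulated 30× individuals recovers ≥ 99% of called genotypes (acceptance
test) — the desk-scale analogue of wet-lab concordance checks on real
cohorts, which require restricted data.

### Cohort filters

`cohort_filter()` removes markers across a cohort when (a) the fraction of
calls with unexpected ploidy (diploid call where haploid expected for that
individual's sex and the marker's chromosome, or any call on a chromosome
the individual lacks) exceeds `max_unexpected` (**0.02**); `NC` calls are
excluded from numerator and denominator; (b) the Hardy–Weinberg exact test
rejects at `hwe_alpha` (**10⁻⁴** — a screening threshold: with thousands of
markers, a loose α would discard many good markers by multiplicity alone);
(c) a REF– marker shows no B allele in the whole cohort (an insertion
never actually observed inserted is most plausibly an artifact), while
monomorphic REF+ markers are kept as explained above. The HWE test is the
conditional exact test: the Levene–Haldane distribution over heterozygote
counts computed by the mid-out recurrence, two-sided p as the sum of
configurations no more probable than observed; it is verified against full
closed-form enumeration for every table with n ≤ 50.

## Simulator

`plant_insertions()` inserts, at uniform random non-N positions of a
genome, the structure `element + polyA + TSD-copy`, where the TSD copy
duplicates the **15** bases 5′ of the breakpoint (so the element is flanked
by the two copies, and the 25 bp discovery flank remains a contiguous
reference substring), the polyA length is uniform on **[5, 80]**, and the
element body receives i.i.d. substitutions at `mutation_rate` (0–0.3;
varying it emulates insertion age, and mutations may destroy the signature
— that lost detectability is part of what is being measured). Insertions
are heterozygous by default, on a random haplotype of a diploid genome
copy; positions, zygosity and polyA lengths are drawn before mutations, so
runs with equal seeds and different mutation rates plant identically.
Elements are planted in forward orientation: the truth record has no
strand, and a reverse-orientation insertion would shift the apparent
breakpoint by the TSD length, past the fixed ±5 bp matching tolerance;
minus-strand discovery is exercised by dedicated fixtures instead.

`simulate_reads()` draws fragments uniformly across haplotypes with length
Normal(**500**, **50**) truncated below at the read length, takes
**151** bp from each end (mate 2 reverse-complemented), and applies
substitution errors at **0.005** per base. These are standard short-read
simulation settings for a modern 150 bp paired-end run; the insert-size SD
is the common simulator default. No indel errors, no quality profiles, no
GC-coverage bias.

`evaluate_discovery()` matches truth to discoveries within ±**5** bp (the
TSD makes the exact reported base convention-dependent; 5 bp is well below
the minimum distance between planted elements) and classifies unmatched
insertions: **FN2** when the reference region the method must read — the
25 bp flank plus the 10 comparison bases — overlaps `N` (a property of the
reference alone, hence independent of mutation rate, which the acceptance
suite asserts exactly); otherwise **FN1** when the flank is not
reference-unique; otherwise *missed-other* (e.g. signature destroyed by
mutation, or support below threshold).

### What a green test does and does not establish

The simulated genomes are i.i.d. random sequence (41% GC). They emulate the
junction geometry, coverage statistics, error load, N-regions and local
duplications — the quantities the algorithms actually interact with — but
not the real genome's repeat landscape: a real genome carries ~1.1 million
existing Alu copies, so the REF– scan sees vastly more signature hits whose
flanks are repetitive, and the realised FN1 rate on human data (roughly a
fifth of insertions) is far higher than on random fixtures. Green tests
establish algorithmic correctness and the direction/shape of the
sensitivity behaviour, not human-genome performance numbers. Relatedly, a
full-scale reference scan (GRCh37-sized, expected to give on the order of
2.7×10⁵ signature hits and ~1.1×10⁵ TSD-bearing candidates) needs the
reference download and ~20 minutes; it is documented here as an external
check and deliberately not part of the test suite.

## Numerical and interface conventions

- All coordinates, internal and user-facing, are 1-based inclusive (the
  R/Bioconductor convention); `to_zero_based()`/`to_one_based()` convert
  for BED-style interoperability and are property-tested as inverse
  bijections.
- K-mer counting is canonical: a k-mer and its reverse complement are one
  marker; palindromic (even-length) k-mers are counted once per site and
  reported on `+`.
- Ties: the TSD search takes the *nearest* downstream copy; the caller
  breaks exact posterior ties by hypothesis order (AA, AB, BB), which can
  only matter at zero information where the posterior threshold forces
  `NC` anyway.
- Degenerate inputs: empty read sets, empty candidate tables and empty pair
  databases flow through as empty tibbles; a pair whose two alleles would
  be identical is dropped at construction and refused at write time.
- Interchange files are versioned TSV with `#key=value` headers; writers
  validate type invariants before writing, so `read(write(x)) = x` holds on
  anything a writer accepts.
- The packaged Alu consensus is a *synthetic* AluY-like sequence
  (`alu_consensus()`): no curated repeat library is bundled, every
  simulation and homology default uses this stand-in, and any multi-record
  FASTA library can be supplied instead (best score over records is used).

## Known limitations

5′-truncated elements are undetectable by construction. Discovery operates
per individual; no joint calling across a cohort. The genotyper assumes the
pair database was filtered (unique A, absent B); feeding unfiltered pairs
inflates ε. Alternative 32-mer splits (22+10 … 24+8) are expected to behave
similarly but only 25+7 is exercised by tests. Other mobile element
families (L1, SVA) have variable 5′ ends and would need gapped signature
sets; the current scanner does not support them.
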