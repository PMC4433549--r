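---
title: "SSR marker development from short reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR marker development from short reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

# The problem

Given one shotgun library of short paired-end reads from a single diploid
individual of a species with no reference genome, produce a ranked list of
microsatellite (SSR) loci worth testing as genetic markers. Reads are cheap;
wet-lab testing of primer pairs is not, so the pipeline's job is to spend
reads to save PCRs: find repeat tracts, keep only loci whose flanks admit
primers and look single-copy, and rank first those loci at which the
sequenced individual itself shows two amplicon lengths — direct evidence of
heterozygosity, hence of polymorphism.

This vignette records the model behind each stage, the tunable parameters
and why their defaults are what they are, the numerical edge cases, and
what the synthetic validation does and does not demonstrate.

# Motif algebra

A repeat motif is a primitive word over {A,C,G,T} of length 2–6 (primitive:
not a power of a shorter word, so "ATAT" is not a motif and homopolymers
are excluded). Two motifs describe the same tandem repeat if one is a
cyclic rotation of the other or of its reverse complement — a tract reads
`(TG)n` on one strand and `(CA)n` on the other, and `(TGG)n` can be phased
as `(GTG)n` or `(GGT)n`. All reporting therefore uses the equivalence class
under the group generated by rotation and reverse complementation, named by
its lexicographically smallest member (deterministic, and it matches how
classes are conventionally labelled: AAG, AAT, ...). Exhaustive enumeration
gives 4 / 10 / 33 / 102 / 350 classes for k = 2..6, which the test suite
cross-checks against an independent graph-components oracle.

# Read quality control

Defaults follow standard survey-sequencing QC: minimum length 50 nt,
minimum mean Phred quality 25 (arithmetic mean of per-base scores, Phred+33
encoding assumed and others rejected), at most one `N`. Rules run cheapest
first (length → ambiguity → quality → DUST) and each read is charged to the
*first* rule it violates, so the reason counts partition the input exactly
— convenient for audit logs.

**Low complexity.** The DUST-style score is computed windowless over the
whole read from overlapping triplet counts `c_t` among the `w` valid
(N-free) windows, scaled to 0–100:

$$S = 100 \cdot \frac{\sum_t c_t (c_t - 1)}{w (w - 1)}$$

0 means all triplets distinct, 100 a homopolymer; reads with S ≥ 7 are
removed, the conventional threshold on this scale. An all-`(AT)` read
scores ≈ 49.5, comfortably above it.

**Duplicates** are exact full-length sequence matches (for pairs, on the
ordered concatenation); the first occurrence is kept. No prefix-duplicate
logic: it buys little at 100 nt and complicates the accounting.

**Pair merging.** The reverse mate is reverse-complemented and slid along
the forward mate's 3' end; the longest overlap ≥ 10 nt with ≤ 10 %
mismatches wins, and disagreeing positions take the higher-quality base.
Two deliberate refinements:

* An overlap search inside a repeat tract is ambiguous — a periodic
  sequence matches at several overlap lengths, and taking the longest
  silently deletes repeat units from the merged super-read, which later
  shows up as spurious ±1-unit amplicon bins in the e-PCR screen. Pairs
  with more than one exactly matching overlap length are therefore left
  unmerged. The information is not lost: their raw mates still enter the
  screening set.
* The mismatch-tolerant search runs only for pairs with no exact overlap.
  A longer imperfect overlap can in principle beat a shorter perfect one,
  but at 10 nt minimum overlap the probability is negligible and skipping
  the full per-pair scan keeps merging vectorized.

The 10 nt / 10 % merge defaults are our choice (the tools this stage
emulates do not publish theirs); both are exposed in `qc_params()`.

# SSR scanning

Only perfect (mismatch-free) tracts are detected, with per-unit-length
minimums of 6 units (dinucleotide), 4 (tri-/tetra-) and 3 (penta-/hexa-).
`N` never matches. Detection is run-length based: positions where
`s[i] == s[i+k]` form runs whose length λ gives a tract of ⌊(λ+k)/k⌋ whole
units; the motif observed at the tract start must itself be primitive
(otherwise the true period is shorter and the smaller k finds it).

Numerical conventions worth stating:

* Coordinates are 0-based half-open everywhere, including TSV export.
* Only whole units are reported (`end − start = units × k`). A partial
  trailing unit is trimmed at the 3' side of whichever strand is scanned;
  consequently the mirror identity `end' = L − start` under reverse
  complementation is exact only for tracts without partial-unit extensions
  (the class/unit multiset is always strand-invariant).
* When candidate tracts of different unit lengths overlap, the tract
  covering more bases wins; ties prefer the shorter motif, then the
  leftmost start. This keeps output deterministic.
* A one-base interruption splits a tract into two loci; a read whose loci
  all share one canonical motif is classified *broken*, with two or more
  distinct motifs *compound*, with one locus *single*. No maximum gap is
  imposed within a read (reads are ≤ ~200 nt).

# Primer design and PAL screening

A locus is a PAL ("potentially amplifiable locus") if both flanks admit a
primer under the default-style constraint set: length 18–27 nt (optimum
20), melting temperature 57–63 °C (optimum 60), GC 20–80 %, mononucleotide
runs ≤ 4, primers strictly outside the tract, product size within a
configurable range (default 100–450 bp, bracketing typical SSR allele
sizes). Dinucleotide loci are excluded from marker development — their
stutter makes them poor markers and the thresholds make them abundant.

Melting temperatures use the unified nearest-neighbour thermodynamic
parameters with entropic salt correction
(ΔS + 0.368 (n−1) ln[Na⁺]) and Tm = 1000·ΔH / (ΔS + R ln C) − 273.15,
at 50 mM monovalent salt with 500 nM primer and 250 nM template strand —
PCR-typical concentrations under which 18–27-mers of moderate GC reach the
57–63 °C window. The tests pin four sequences against an independent
published NN calculator at the same parameter set (agreement ≪ 0.5 °C).

Candidate pairs are scored by deviation from the length and Tm optima;
ties break to the leftmost forward primer, then the smallest product. An
optional product-size optimum term (off by default) mirrors the product
penalty of standard design tools; it matters when amplicons must be
observed *within reads* — support for a product of length P on super-reads
of length W decays like (W − P), so a screen run at read scale should ask
for small products. The pipeline wrapper uses product range 50–120 bp with
optimum 60 for exactly this reason.

**Single-copy screening** operationalizes "most stringent criteria" as:
every exact occurrence of either primer (both strands) in the read set
must be consistent with the PAL's own locus — an occurrence in a read
whose SSR tract has a different canonical motif, or a primer shared
between PALs of different canonical motifs, rejects the PAL. With no reads
the screen is vacuous and says so via an attribute. The operation is
idempotent.

# In-silico PCR and the heterozygosity pre-screen

For each PAL, every read (both orientations) containing the forward primer
followed 3' by the reverse complement of the reverse primer contributes an
amplicon observation of that product length. A locus is flagged
potentially polymorphic when its length histogram has ≥ 2 bins, each
supported by ≥ 2 reads, separated by at least one repeat-unit length.
The support threshold guards against residual sequencing error and the
unit-multiple rule discards sub-unit noise — SSR alleles differ by unit
multiples. Both thresholds are exposed; their defaults are our choice, as
is the ranking (flagged loci first, by allele-length spread then read
support, stable order otherwise).

# K-mer spectrum and genome size

K-mers (default k = 21, canonical strand = lexicographic minimum of k-mer
and reverse complement) are counted exactly by packing bases into 2-bit
numeric codes (k ≤ 25 keeps codes inside double precision). The
multiplicity histogram is smoothed with a 3-wide moving average; the first
local minimum *behind which a higher peak rises* is the error cutoff (the
qualifier matters: without it a degenerate spike spectrum places the
"valley" after the peak). Error-free data have no error peak; the cutoff
falls back to 0 with a warning, and a monotone histogram is an estimation
failure. The coverage peak is the raw-histogram mode above the cutoff,
refined to sub-integer precision by an iterated local centroid over a
window of ~2 Poisson standard deviations — the raw mode's ±1 jitter alone
would cost up to ~6 % in size. Genome size is then (k-mer instances above
the cutoff) / (refined peak). K-mers with multiplicity ≥ 50 constitute the
repeat fraction.

# The synthetic validation, and what it shows

`simulate_genome` draws i.i.d. bases (default GC 0.38, a typical dicot
genome-wide value). `plant_ssrs` spaces loci evenly, wraps each tract in
freshly drawn flanks (default 120 nt per side at GC 0.5, primer-friendly),
and rejection-samples those flanks until the planted context scans to
exactly the intended tract — no accidental repeat signal, no phase
extension into the tract — and, optionally, until a primer pair exists
within 50 nt of the tract, making every planted locus potentially
amplifiable by construction. Heterozygous loci differ between haplotypes
only in repeat-unit count. `simulate_reads` draws fragments uniformly,
50/50 from the two haplotypes, with i.i.d. substitutions (no indels:
short-read errors are substitution-dominated, and indel errors would
confound a length-based screen by design).

The validation experiment plants 10 heterozygous (allele difference 2
units) and 10 homozygous loci, each with a distinct canonical motif, in a
100 kb diploid, sequenced error-free at 30× as 2×100 nt pairs with
fragment length 180 ± 8. Problem sizes were chosen so that the expected
number of merged super-reads spanning a 60–120 bp product at 15× per
haplotype is ~7–9 per allele, comfortably above the 2-read support
threshold. The pipeline recovers 10/10 heterozygous loci and flags 0/10
homozygous loci; scan recall and precision against the planted truth are
1.0 on reads wholly containing a tract; and genome size is recovered
within 5 % across 50–500 kb genomes at 20–40×. (These statements are
exactly the ones the test suite computes; run it to reproduce them.)

What this does *not* show: performance on real data with indel errors,
PCR/optical duplicates, GC-biased coverage, adapter read-through,
imperfect (interrupted or degenerate) repeats, or paralogous repeat
families sharing flanks. The simulator deliberately omits all of these;
clean flanks in particular make single-copy screening easier than in a
real genome, where the screen's exact-match context rule is conservative
and can reject markers that would amplify fine.

# Known limitations

* Perfect tracts only; an imperfect-repeat aligner is out of scope.
* Exact-match primer search in e-PCR and single-copy screening (no
  mismatch model — none is published for the procedure this follows).
* The published-panel statistics module reports what the packaged table
  computes; two printed figures (a mean allele count of 4.8, and P < 0.005
  for the 37/82 vs 9/13 polymorphism-rate comparison) are not reproducible
  from the printed data themselves (the table computes 4.91, and Pearson's
  chi-square on those counts is 2.61, p ≈ 0.11); the package reports the
  computed values and documents the discrepancy rather than forcing
  agreement.
* M13 tails and GTTT pigtails used for fluorescent genotyping are
  report-time decorations; they are never part of primer matching and are
  not included in primer sequences.
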