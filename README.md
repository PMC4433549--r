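# ssrkit

Microsatellite (SSR) marker development from short sequencing reads.

Developing polymorphic SSR markers for a non-model organism from a single
shotgun library involves a chain of small but fiddly steps: quality-filter
the reads, find perfect repeat tracts, group equivalent repeat motifs,
decide which loci admit PCR primers in their flanks ("potentially
amplifiable loci", PALs), and — before ordering any oligos — pre-screen the
reads themselves for loci where the sequenced individual already shows two
amplicon lengths, i.e. is likely heterozygous. `ssrkit` implements that
chain for R users (conservation geneticists, breeders, anyone building a
marker panel on a budget), together with k-mer-spectrum genome-size
estimation, summary statistics for a published marker panel, and a diploid
read simulator with planted repeat loci so the whole pipeline can be
validated against known ground truth.

## The pieces

* **Motif algebra.** Repeat motifs are grouped into equivalence classes
  under cyclic rotation and reverse complementation (TG ≡ CA; TGG ≡ GTG ≡
  GGT), named by the lexicographically smallest member. There are 4
  dinucleotide classes, 10 trinucleotide, 33 tetra-, 102 penta- and 350
  hexanucleotide classes; homopolymers are excluded because they are not
  primitive units.
* **Read QC** (`quality_filter`, `dust_score`, `deduplicate`,
  `merge_pairs`): length ≥ 50 nt, mean Phred ≥ 25, ≤ 1 ambiguous base,
  DUST low-complexity score < 7, exact-duplicate removal, and overlap
  merging of mates into super-reads (with refusal of repeat-periodic
  ambiguous overlaps).
* **SSR scanning** (`scan_reads`): all maximal perfect tracts with ≥ 6
  units for dinucleotides, ≥ 4 for tri/tetra, ≥ 3 for penta/hexa; reads
  with several tracts are classified *compound* (different motifs) or
  *broken* (same motif, interrupted).
* **Primer design and PAL screening** (`design_primer_pair`, `find_pals`,
  `screen_single_copy`): length 18–27 nt (optimum 20), nearest-neighbour
  Tm 57–63 °C (optimum 60; unified NN parameters, 50 mM Na⁺, 500 nM
  primer), GC 20–80 %, mononucleotide runs ≤ 4, primers outside the tract;
  single-copy screening rejects primers whose exact matches occur in
  conflicting repeat contexts.
* **In-silico PCR** (`epcr_amplicons`, `flag_potentially_polymorphic`): a
  locus whose amplicon lengths form ≥ 2 read-supported bins one repeat unit
  apart is flagged putatively heterozygous and ranked first for wet-lab
  testing.
* **K-mer spectrum** (`kmer_spectrum`, `estimate_genome_size`,
  `extract_repeat_kmers`): canonical-strand k-mer counting (default
  k = 21), genome size = k-mer instances above the error cutoff divided by
  the coverage-peak multiplicity, and extraction of the ≥ 50× repeat
  fraction.
* **Simulator** (`simulate_genome`, `plant_ssrs`, `simulate_reads`):
  diploid genomes with planted single/compound/broken loci, heterozygous
  repeat-length alleles, uniform-coverage 2×100 nt pairs and an i.i.d.
  substitution error model.

## Worked example

The packaged marker panel (`inst/extdata/table1_markers.tsv`, 46
markers for the frankincense tree *Boswellia papyrifera* with
cross-amplification calls for *B. pirrotae* and *B. popoviana*):

```r
library(ssrkit)
panel <- parse_marker_table()
nrow(panel)
#> [1] 46
table(classify_marker(panel$motif))
#>  hexa penta tetra   tri
#>     6     6     4    30
allele_stats(panel)
#> $min 2   $max 12   $mean 4.91
mean_observed_het(panel)
#> [1] 0.43
cross_species_summary(panel, "pirrotae")$het
#> [1] 19
```

So the panel holds 46 markers (30 tri-, 4 tetra-, 6 penta-, 6
hexanucleotide), 2–12 alleles per locus (mean 4.91), mean observed
heterozygosity 0.43 across ten genotypes, and at least 19 markers
polymorphic in *B. pirrotae*. Scanning a read with a compound repeat:

```r
scan_read(paste0("CATG", strrep("TC", 10), strrep("AGCG", 5), "GGAT"))
#>   read_id start end motif canonical units
#> 1   read1     4  24    TC        AG    10
#> 2   read1    24  44  AGCG      AGCG     5
round(ssr_density(175607, 5e6 * 200), 1)   # kb of sequence per SSR locus
#> [1] 5.7
```

(Coordinates are 0-based half-open; `TC` reports canonical class `AG`.)

The end-to-end simulation workflow — plant 10 heterozygous and 10
homozygous loci in a 100 kb diploid, sequence error-free at 30×, then run
QC → merge → scan → design → e-PCR — is in the methods vignette
(`vignettes/ssr-marker-development.Rmd`); it recovers all 10 heterozygous
loci and flags none of the homozygous ones.

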