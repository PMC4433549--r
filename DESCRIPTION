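Package: ssrkit
Title: Microsatellite Marker Development from Short Sequencing Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for developing simple sequence repeat (SSR, microsatellite)
    markers from short-read shotgun data of non-model organisms. Covers read
    quality control (length, mean quality, ambiguity, DUST low-complexity and
    duplicate filtering, paired-end overlap merging), detection of perfect SSR
    tracts with canonical motif classes under rotation and reverse-complement
    equivalence, flanking-primer design with nearest-neighbour melting
    temperatures, single-copy screening of potentially amplifiable loci (PALs),
    in-silico PCR pre-screening for length-polymorphic (putatively heterozygous)
    loci, k-mer spectrum genome-size estimation, marker-panel summary statistics
    and cross-species transferability tallies, and a diploid read simulator with
    planted SSR loci for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
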