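Package: dipr
Title: Divergence-Based Polarization of Introgression in Four-Taxon Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the direction and asymmetry of introgression between two
    lineages in a four-taxon system (P1, P2, P3, outgroup) from genome-wide
    patterns of pairwise sequence divergence.  Loci are classified by the
    topology of per-locus neighbor-joining gene trees, and divergence-shift
    statistics (the delta-K profile, delta-delta-K, and the ILS-corrected
    delta-delta-delta-K) are computed with locus-bootstrap significance,
    yielding a categorical call of introgression directionality.  Includes a
    structured-coalescent simulator with a directional lineage-transfer event
    and HKY sequence evolution for generating labeled synthetic four-taxon
    genomes (per-locus or whole-chromosome with recombination blocks), window
    partitioning of chromosome alignments, taxon-role mapping, and parameter
    scan drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
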