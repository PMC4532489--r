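Package: popadmix
Title: Continental and Sub-Continental Ancestry from mtDNA Haplotypes and
    Autosomal Ancestry-Informative Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population ancestry analysis in admixed human
    populations. Parses mtDNA control-region haplotypes written as
    rCRS-relative variant strings, classifies them against a loadable
    haplogroup tree and partitions samples into continental ancestry
    components. Computes Nei sequence diversity indices (haplotype
    diversity, nucleotide diversity, segregating sites, mean pairwise
    differences) on a common control-region segment. Estimates
    sub-continental admixture proportions by haplotype sharing against
    region-labelled reference databases with step-mutation tolerance
    (P0/P1/P2) and bootstrap confidence intervals. Estimates supervised
    continental ancestry from biallelic ancestry-informative markers by
    maximum likelihood (EM), with identity-by-state distances and
    classical multidimensional scaling. Includes a synthetic-data
    generator (region-structured haplotype pools, admixed targets,
    Balding-Nichols genotype panels) so the full pipeline can be
    exercised with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
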