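Package: admixtrace
Title: Tracing Admixed Origins of Crop Populations from SNP Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the hybrid origin of a crop population from
    genome-wide SNP data. Harmonizes and merges biallelic genotype matrices
    called against a shared reference, selects typical group representatives
    on principal-component coordinates, classifies sites by joint allele
    frequencies between a focal group and a putative parent, scores
    individuals for carriage of the focal group's distinguishing alleles,
    builds median-joining networks of organellar haplotypes, paints local
    ancestry of phased haplotypes with a switch-penalty copying-model
    dynamic program, and calibrates ancestry estimates with in-silico
    recombinants of known mosaic structure. Includes a forward simulator
    (Balding-Nichols source populations, tract-structured admixture,
    depth-asymmetric missingness, maternally inherited organellar
    haplotypes) so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
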