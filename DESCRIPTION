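Package: aboseq
Title: Full-Gene ABO Allele Assignment, Intronic Marker Derivation and
    Recombination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the ABO blood-group gene from variant calls
    spanning the start codon to the stop codon. Implements HGVS c.-notation
    coordinate arithmetic over a configurable exon/intron gene model, diploid
    ABO allele assignment from coding-region zygosity profiles against an
    allele-definition table, derivation of allele-specific intronic SNV
    catalogs from homozygote panels, annotation of the erythroid
    cell-specific regulatory element in intron 1, inference of intragenic
    allele-recombination breakpoint intervals from marker zygosity patterns,
    read-backed phasing of novel variants, in-silico long-range PCR, and a
    deterministic synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'aboseq-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'hgvs.R'
    'gene-model.R'
    'reference.R'
    'insilico-pcr.R'
    'profiles.R'
    'vcf.R'
    'allele-table.R'
    'genotype.R'
    'regulatory.R'
    'markers.R'
    'recombination.R'
    'phasing.R'
    'simulate.R'
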