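Package: allotrio
Title: Trio-Based Allopolyploid Detection and Doubled-Haploid Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-sample variant calls from doubled-haploid
    (homozygous diploid) algal cultures, as used in nori (Pyropia) breeding
    genomics. Provides genotype-quality and site-missingness filtering,
    heterozygous-locus removal for homozygosity-expected samples, trio-based
    detection of allotetraploid interspecific hybrids at parental
    fixed-difference loci, identity-by-state distances with classical
    multidimensional scaling, phenotype-group-specific variant screens,
    variable-site alignment export with parsimony-informative site
    accounting, chloroplast-versus-mitochondrial substitution-rate
    comparison, and a ground-truth simulator that emulates the whole study
    design (clustered doubled-haploid genomes, a diverged sister species, an
    allotetraploid F1, uniparental organelle inheritance, genotyping noise)
    so that every stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    phangorn,
    rlang,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
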