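Package: stuntscan
Title: Mapping a Recessive Growth-Stunting Locus: Autozygosity, Splice-Isoform
    and Gene-Dropping Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for mapping a recessive juvenile
    growth-stunting locus in a livestock population. Provides readers and
    writers for pedigree, SNP-genotype, qPCR and prospective-cohort tables;
    a synthetic-data generator (multi-generation pedigree descending from a
    founder carrier, gene dropping of a tagged ancestral haplotype with
    Haldane recombination and transmission distortion, prospective cohort
    outcomes, and qPCR quantification cycles); runs-of-homozygosity detection
    and cross-case intersection to localize a shared autozygous interval;
    Monte-Carlo gene dropping with an exact enumeration oracle, tail
    probabilities for observed carrier counts and a transmission-rate
    compatibility scan; qPCR relative quantification (standard-curve
    efficiency, geNorm reference stability, normalized relative quantities)
    with a two-isoform nonsense-mediated-decay model solving for exon-skip
    and cryptic-splice fractions; and cohort statistics (Hardy-Weinberg
    expectations, segregation and exact genotype-by-outcome tests, linkage
    disequilibrium, per-genotype growth regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
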