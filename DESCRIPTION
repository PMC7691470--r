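Package: yhapnet
Title: Y-Chromosome Haplogroup Discovery from SNP Genotypes via
    Linkage-Disequilibrium Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers male-limited (Y-chromosome) haplogroups from diploid
    biallelic SNP genotypes in species with undifferentiated sex chromosomes,
    such as salmonids. SNPs are filtered for missingness, minor allele
    frequency and collapsed-paralog artifacts (heterozygosity and allele
    read-ratio deviation), pairwise linkage disequilibrium is estimated with a
    two-locus EM composite r-squared, long-range high-LD SNP sets are
    extracted as network components, genotypes are phased by
    partition-ligation EM, and phased haplotypes are clustered with Ward's
    criterion into X- and Y-type haplogroups. Diagnostic SNP panels are built
    from fixed allele-frequency differences and new samples are assigned to
    haplogroups by expected-genotype matching or joint clustering.
    Associations between haplogroups and length or age at maturity are tested
    by two-factor analysis of variance with Tukey post hoc comparisons and
    compact letter displays. A seeded synthetic-data generator with planted
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
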