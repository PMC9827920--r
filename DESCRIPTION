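Package: paleokin
Title: Kinship, Pedigree and Population-Affinity Inference for Low-Coverage
    Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing genetic kinship and population affinity
    from low-coverage ancient genomes genotyped on SNP capture panels.
    Reads and writes EIGENSTRAT genotype data, produces pseudo-haploid calls
    and coverage-based genetic sex assignments, estimates pairwise relatedness
    by the pairwise mismatch rate (PMR) and by maximum-likelihood IBD
    coefficients (k0, k1, k2) computed from genotype likelihoods, enumerates
    pedigrees consistent with pairwise degrees and uniparental (mitochondrial
    and Y) haplogroups, computes outgroup-f3 and f4 statistics with weighted
    block-jackknife standard errors, and fits qpWave-style rank tests and
    qpAdm-style admixture weights. A synthetic-data module simulates
    pedigree-structured genotypes, low-coverage read counts and
    admixture-graph allele frequencies with known ground truth so that every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
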