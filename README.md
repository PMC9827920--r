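# paleokin

Kinship, pedigree and population-affinity inference for low-coverage ancient
DNA.

## The problem

Ancient genomes are usually sequenced at well below 1x coverage, so diploid
genotypes cannot be called reliably. The field's standard workaround is the
*pseudo-haploid* call: one randomly sampled sequencing base per SNP per
individual, typically on a capture panel of ~1.2 million ancestry-informative
sites. From such data, archaeogenetic studies routinely need to answer three
questions about a group of co-buried individuals:

1. **Who is related to whom, and how closely?** The *pairwise mismatch rate*
   (PMR) between two individuals' single sampled alleles has expectation
   `(1 - kappa) * b`, where `kappa` is the kinship coefficient (1/4 for
   first-degree, 1/8 second, 1/16 third) and `b` the mismatch rate of
   unrelated pairs from the same population. Normalizing each pair's PMR by
   `b` and assigning it to the nearest of `{0.5, 0.75, 0.875, 0.9375, 1}`
   classifies the relationship degree. Parent-offspring and full-sibling
   pairs have identical `kappa` but different IBD-sharing profiles
   (`(k0, k1, k2) = (0, 1, 0)` versus `(1/4, 1/2, 1/4)`), which `paleokin`
   separates by maximum-likelihood estimation of `(k0, k1, k2)` from
   genotype likelihoods (the lcMLkin model) with an accelerated EM on the
   probability simplex.
2. **What pedigree explains the pairwise estimates?** A bounded exhaustive
   search enumerates pedigrees (with unsampled "latent" connectors) whose
   expected degrees reproduce the observed degree matrix, then ranks them by
   consistency with mitochondrial haplogroups along maternal lines, Y
   haplogroups along paternal lines, parent sexes and age classes. All
   co-maximal alternatives are reported, never a silently chosen winner.
3. **Which populations does the group resemble?** Outgroup-f3 statistics
   rank genetic affinity; f4 statistics test cladality; qpWave-style rank
   tests and qpAdm-style generalized-least-squares admixture weights model
   the group as a mixture of source populations, all with standard errors
   from a weighted 5 cM block jackknife.

A synthetic-data module simulates pedigree-structured diploid genotypes
(HWE founders, Mendelian transmission over unlinked SNPs), low-coverage
read counts (Poisson depth, base error, contamination), pseudo-haploid
calls, uniparental haplogroup transmission and admixture-graph allele
frequencies, so that every stage of the pipeline can be validated against
known ground truth without any external data. An osteological helper
computes the minimum number of individuals (MNI) from skeletal element
counts: per element and age class, MNI is the greatest of the left / right /
unsided counts, and the assemblage MNI is the per-age-class maximum over
elements.

## Worked example

Skeletal element counts (bundled table from a sixth-century jar-coffin
assemblage) to MNI:

```r
library(paleokin)
tab <- read_element_counts(system.file("extdata",
        "gunsan_element_counts.tsv", package = "paleokin"))
res <- total_mni(tab)
#> adult MNI 6, subadult MNI 3, total 9
```

Kinship on a simulated extended family — a couple, their two children, a
son of the mother by another partner, and a paternal half-uncle of the
father — genotyped at 50,000 pseudo-haploid SNPs:

```r
fam  <- family_test_pedigree()
cfg  <- sim_config(n_snps = 5e4, seed = 42)
p    <- draw_allele_frequencies(cfg)
sim  <- simulate_pedigree_genotypes(fam$spec, p, seed = 43)
hap  <- pseudo_haploidize(sim$genotypes, seed = 44)
ref  <- sample_individuals_from_freqs(matrix(p, dimnames = list(NULL, "ref")),
                                      20, seed = 45)
b    <- background_pmr(pseudo_haploidize(ref$genotypes, seed = 46),
                       autosomes_only = FALSE)
kin  <- classify_all_pairs(hap, b, ids = fam$observed, autosomes_only = FALSE)
kin[, c("id1", "id2", "pmr", "normalized_pmr", "degree")]
#>    id1 id2   pmr normalized_pmr    degree
#> 2  FTH SON 0.249          0.748     first
#> 8  MTH UNC 0.252          0.755     first
#> 11 SON UNC 0.288          0.865    second
#> 5  FTH REL 0.308          0.923     third
#> 1  FTH MTH 0.333          0.999 unrelated
#> ...
prune_relatives(kin)
#> [1] "FTH" "MTH" "REL"
```

The normalized PMR values sit on the expected ladder: ~0.75 for the six
first-degree pairs, ~0.875 for the uncle-nephew pairs, ~0.94 for the
third-degree pair, ~1 for unrelated pairs. Pruning relatives up to second
degree keeps a maximum unrelated subset of three of the six individuals.
`run_kinship_pipeline()` chains these stages with read-level `(k0, k1, k2)`
typing and pedigree enumeration; `run_popgen_pipeline()` does the same for
the f3 / f4 / qpWave / qpAdm stage.

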