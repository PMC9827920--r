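# shared fixtures built in code

# a small panel over two autosomes plus X
small_panel <- function(n = 10, with_x = FALSE) {
  chrom <- rep(c("1", "2"), length.out = n)
  if (with_x) chrom[n] <- "X"
  chrom <- chrom[order(match(chrom, c("1", "2", "X")))]
  snp_panel(sprintf("rs%03d", seq_len(n)), chrom,
            physical_position = ave(seq_len(n), chrom, FUN = seq_along) * 1000L,
            genetic_position = ave(seq_len(n), chrom, FUN = seq_along) * 0.5)
}

random_genotypes <- function(n_ind, n_snp, ploidy = "diploid",
                             missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  hi <- if (ploidy == "haploid") 1L else 2L
  calls <- matrix(sample(0:hi, n_ind * n_snp, replace = TRUE), nrow = n_ind)
  calls[matrix(runif(n_ind * n_snp) < missing_rate, nrow = n_ind)] <- NA_integer_
  genotype_matrix(calls, ploidy, sprintf("ind%02d", seq_len(n_ind)))
}

# observed-pair degree matrix of the extended-family pedigree, derived from
# the pedigree structure itself
family_degrees <- function() {
  fam <- family_test_pedigree()
  spec <- fam$spec
  ped <- pedigree(spec$id, spec$sex, spec$father, spec$mother,
                  observed = spec$id %in% fam$observed)
  prs <- utils::combn(fam$observed, 2)
  data.frame(id1 = prs[1, ], id2 = prs[2, ],
             degree = vapply(seq_len(ncol(prs)), function(k)
               expected_kinship(ped, prs[1, k], prs[2, k])$degree,
               character(1)),
             stringsAsFactors = FALSE)
}

# the pairs of the family pedigree that are parent-offspring / full sibs
family_first_degree_types <- function() {
  data.frame(id1 = c("FTH", "FTH", "MTH", "MTH", "MTH", "SON"),
             id2 = c("SON", "DAU", "SON", "DAU", "UNC", "DAU"),
             type = c("parent_offspring", "parent_offspring",
                      "parent_offspring", "parent_offspring",
                      "parent_offspring", "full_sibling"),
             stringsAsFactors = FALSE)
}

# admixture graph used for qpAdm validation: target T = alpha*S1 + (1-alpha)*S2
admixture_test_graph <- function(alpha = 0.3) {
  data.frame(
    pop     = c("root", "O", "anc", "A1", "A2", "S1", "R1", "S2", "R2", "R3", "T"),
    parent1 = c(NA, "root", "root", "anc", "anc", "A1", "A1", "A2", "A2", "anc", "S1"),
    parent2 = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, "S2"),
    alpha   = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, alpha),
    drift   = c(0, 0.1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.05, 0.005),
    stringsAsFactors = FALSE)
}

# graph with a single left population L, used for null calibrations
cladal_test_graph <- function() {
  data.frame(
    pop     = c("root", "O", "anc", "L", "R1", "R2", "R3", "R4"),
    parent1 = c(NA, "root", "root", "anc", "anc", "anc", "root", "anc"),
    parent2 = NA, alpha = NA,
    drift   = c(0, 0.1, 0.02, 0.02, 0.03, 0.03, 0.08, 0.05),
    stringsAsFactors = FALSE)
}

# pseudo-haploidize then mask a fraction of calls (per-individual missingness)
mask_calls <- function(hap, missingness, seed) {
  set.seed(seed)
  m <- matrix(runif(length(hap$calls)) < missingness, nrow = nrow(hap$calls))
  hap$calls[m] <- NA_integer_
  hap
}

# simulate the family, pseudo-haploidize with missingness, classify all
# 15 observed pairs against a reference-panel baseline
classify_family_once <- function(freqs, baseline_b, seed, missingness = 0.5) {
  fam <- family_test_pedigree()
  sim <- simulate_pedigree_genotypes(fam$spec, freqs, seed = seed)
  hap <- pseudo_haploidize(sim$genotypes, seed = seed + 1L)
  hap <- mask_calls(hap, missingness, seed + 2L)
  classify_all_pairs(hap, baseline_b, ids = fam$observed,
                     autosomes_only = FALSE)
}
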