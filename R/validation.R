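#' Replicated validation experiments
#'
#' These harness functions re-run the package's main inference stages on
#' synthetic data with known ground truth and summarize how often the truth
#' is recovered. They are used by the package's acceptance checks and are
#' exported so that the full validation can be reproduced from a script.
#'
#' @name validation
NULL

#' Degree-count recovery for the extended-family pedigree
#'
#' Simulates the [family_test_pedigree()] at `n_snps` unlinked SNPs,
#' pseudo-haploidizes with per-call missingness, classifies all 15 observed
#' pairs against a baseline from a simulated unrelated reference panel, and
#' tallies the degree counts per replicate. The family's true counts are 6
#' first-degree, 2 second-degree and 1 third-degree pair; the two pairs
#' linking the paternal relative to the children are truly fourth degree,
#' whose expected normalized mismatch rate lies exactly on the
#' third/unrelated classification boundary.
#'
#' @param n_reps number of seeded replicates.
#' @param n_snps SNPs per replicate.
#' @param missingness per-call missing probability after pseudo-haploid
#'   sampling.
#' @param seed master seed.
#' @param n_ref reference-panel individuals for the baseline.
#' @return data frame with one row per replicate: counts of first, second,
#'   third-degree calls among the 15 pairs and `exact` (TRUE when the
#'   counts equal 6/2/1).
#' @export
degree_recovery_experiment <- function(n_reps = 100, n_snps = 1e5,
                                       missingness = 0.5, seed = 1,
                                       n_ref = 20) {
  fam <- family_test_pedigree()
  cfg <- sim_config(n_snps = n_snps, seed = derive_seed(seed, 10L))
  freqs <- draw_allele_frequencies(cfg)
  ref <- sample_individuals_from_freqs(
    matrix(freqs, dimnames = list(NULL, "ref")), n_ref,
    seed = derive_seed(seed, 11L))
  ref_hap <- pseudo_haploidize(ref$genotypes, seed = derive_seed(seed, 12L))
  b <- background_pmr(ref_hap, autosomes_only = FALSE)$b

  rows <- lapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, 100L + r)
    sim <- simulate_pedigree_genotypes(fam$spec, freqs, seed = s)
    hap <- pseudo_haploidize(sim$genotypes, seed = s + 1L)
    if (missingness > 0) {
      hap <- with_seed(s + 2L, {
        m <- matrix(stats::runif(length(hap$calls)) < missingness,
                    nrow = nrow(hap$calls))
        hap$calls[m] <- NA_integer_
        hap
      })
    }
    kin <- classify_all_pairs(hap, b, ids = fam$observed,
                              autosomes_only = FALSE)
    counts <- table(factor(kin$degree, levels = c("identical", "first",
                                                  "second", "third",
                                                  "unrelated")))
    data.frame(first = as.integer(counts["first"]),
               second = as.integer(counts["second"]),
               third = as.integer(counts["third"]))
  })
  out <- do.call(rbind, rows)
  out$exact <- out$first == 6L & out$second == 2L & out$third == 1L
  out
}

#' End-to-end first-degree typing and pedigree recovery at read level
#'
#' Simulates the family at read level (Poisson depth), runs the full
#' kinship pipeline (pseudo-haploid classification, genotype-likelihood IBD
#' coefficients for first-degree pairs, pedigree enumeration) and reports
#' the IBD typing table together with structural checks on the co-maximal
#' pedigrees: whether the true structure is present, and whether the
#' mother's first-degree relative is placed as her son (the
#' mt-consistency-preferred option).
#'
#' @param seed master seed.
#' @param n_snps SNPs simulated.
#' @param mean_depth Poisson mean sequencing depth.
#' @return list with `typing` (pair, k0, k1, k2, type, truth), `pedigrees`
#'   (the `pedigree_set`), `true_structure_comaximal` and
#'   `maternal_option_comaximal` logicals.
#' @export
family_read_level_experiment <- function(seed = 1, n_snps = 1e5,
                                         mean_depth = 2) {
  fam <- family_test_pedigree()
  cfg <- sim_config(n_snps = n_snps, mean_depth = mean_depth,
                    base_error = 0.01, seed = derive_seed(seed, 20L))
  freqs <- draw_allele_frequencies(cfg)
  sim <- simulate_pedigree_genotypes(fam$spec, freqs,
                                     seed = derive_seed(seed, 21L))
  obs <- genotype_matrix(sim$genotypes$calls[fam$observed, ], "diploid",
                         fam$observed)
  rc <- simulate_reads(obs, cfg, seed = derive_seed(seed, 22L))
  hap <- pseudo_haploidize(rc, seed = derive_seed(seed, 23L))
  report <- suppressWarnings(run_kinship_pipeline(list(
    genotypes = hap, meta = fam$meta, reference = 1 / 3, freqs = freqs,
    read_counts = rc, seed = seed)))
  typing <- report$first_degree_types
  if (!is.null(typing)) {
    truth_type <- family_po_fs_truth()
    key <- paste(pmin(typing$id1, typing$id2), pmax(typing$id1, typing$id2))
    typing$truth <- truth_type[key]
  }
  peds <- report$pedigrees
  comax <- lapply(peds$co_maximal, function(i) peds$reports[[i]]$pedigree)
  has_true <- any(vapply(comax, function(p) {
    pf <- p$father[match("FTH", p$id)]
    if (is.na(pf)) return(FALSE)
    gpa <- p$father[match(pf, p$id)]
    !is.na(gpa) && identical(p$father[match("REL", p$id)], gpa)
  }, logical(1)))
  maternal <- length(comax) > 0 && all(vapply(comax, function(p)
    identical(p$mother[match("UNC", p$id)], "MTH"), logical(1)))
  list(typing = typing, pedigrees = peds,
       true_structure_comaximal = has_true,
       maternal_option_comaximal = maternal,
       kinship_table = report$kinship_table)
}

# true first-degree types of the family pedigree, keyed by sorted pair ids
family_po_fs_truth <- function() {
  c("FTH SON" = "parent_offspring", "DAU FTH" = "parent_offspring",
    "MTH SON" = "parent_offspring", "DAU MTH" = "parent_offspring",
    "MTH UNC" = "parent_offspring", "DAU SON" = "full_sibling")
}

#' Null calibration of the f4 statistic under cladality
#'
#' Simulates a population tree in which the two test populations are
#' independent samples of the same population (a true clade relative to the
#' reference), computes `f4(O, R1; A, B)` per replicate and returns the Z
#' scores, which should rarely exceed |3|.
#'
#' @param n_reps replicates.
#' @param n_snps SNPs per replicate.
#' @param n_per_pop individuals sampled per population.
#' @param seed master seed.
#' @return numeric vector of Z scores.
#' @export
f4_null_experiment <- function(n_reps = 100, n_snps = 2e4, n_per_pop = 12,
                               seed = 1) {
  graph <- null_test_graph()
  blk <- assign_jackknife_blocks(synthetic_snp_panel(n_snps))
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_snps = n_snps, seed = derive_seed(seed, 300L + r))
    fr <- simulate_admixture_freqs(graph, cfg)
    fr2 <- cbind(fr, LA = fr[, "L"], LB = fr[, "L"])
    samp <- sample_individuals_from_freqs(
      fr2[, c("LA", "LB", "O", "R1")], n_per_pop,
      seed = derive_seed(seed, 600L + r))
    gf <- group_frequencies(samp$genotypes, samp$populations)
    f4(gf, "O", "R1", "LA", "LB", blk)$z
  }, numeric(1))
}

#' Null calibration of the qpWave rank-0 test
#'
#' The two left populations are independent samples of one population, so
#' rank 0 holds and the tail probability should be uniform; returns the
#' p-values.
#'
#' @inheritParams f4_null_experiment
#' @return numeric vector of p-values.
#' @export
qpwave_null_experiment <- function(n_reps = 200, n_snps = 1e5,
                                   n_per_pop = 12, seed = 1) {
  graph <- null_test_graph()
  blk <- assign_jackknife_blocks(synthetic_snp_panel(n_snps))
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_snps = n_snps, seed = derive_seed(seed, 900L + r))
    fr <- simulate_admixture_freqs(graph, cfg)
    fr2 <- cbind(fr, LA = fr[, "L"], LB = fr[, "L"])
    samp <- sample_individuals_from_freqs(
      fr2[, c("LA", "LB", "O", "R1", "R2", "R3", "R4")], n_per_pop,
      seed = derive_seed(seed, 1200L + r))
    gf <- group_frequencies(samp$genotypes, samp$populations)
    qpwave_rank_test(gf, c("LA", "LB"), c("O", "R1", "R2", "R3", "R4"),
                     blk, rank = 0)$p_value
  }, numeric(1))
}

#' Recovery of a two-way admixture proportion by qpAdm
#'
#' Simulates a target formed as `alpha * S1 + (1 - alpha) * S2` (plus its
#' own drift), samples individuals, and fits the two-source qpAdm model per
#' replicate.
#'
#' @param n_reps replicates.
#' @param n_snps SNPs per replicate.
#' @param alpha true mixing proportion on the first source.
#' @param n_per_pop individuals sampled per population.
#' @param seed master seed.
#' @return data frame with `weight`, `se` and `hit` (within 2 jackknife
#'   s.e. of `alpha`).
#' @export
qpadm_recovery_experiment <- function(n_reps = 100, n_snps = 1e5,
                                      alpha = 0.3, n_per_pop = 15,
                                      seed = 1) {
  graph <- data.frame(
    pop     = c("root", "O", "anc", "A1", "A2", "S1", "R1", "S2", "R2", "R3", "T"),
    parent1 = c(NA, "root", "root", "anc", "anc", "A1", "A1", "A2", "A2", "anc", "S1"),
    parent2 = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, "S2"),
    alpha   = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, alpha),
    drift   = c(0, 0.1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.05, 0.005),
    stringsAsFactors = FALSE)
  blk <- assign_jackknife_blocks(synthetic_snp_panel(n_snps))
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_snps = n_snps, seed = derive_seed(seed, 1500L + r))
    fr <- simulate_admixture_freqs(graph, cfg)
    samp <- sample_individuals_from_freqs(
      fr[, c("T", "S1", "S2", "O", "R1", "R2", "R3")], n_per_pop,
      seed = derive_seed(seed, 1800L + r))
    gf <- group_frequencies(samp$genotypes, samp$populations)
    res <- qpadm_weights(gf, "T", c("S1", "S2"), c("O", "R1", "R2", "R3"),
                         blk)
    data.frame(weight = unname(res$weights["S1"]),
               se = unname(res$se["S1"]))
  })
  out <- do.call(rbind, rows)
  out$hit <- abs(out$weight - alpha) <= 2 * out$se
  out
}

# drift tree used for the null experiments: L, R1, R2, R4 inside one clade,
# R3 and the outgroup O outside it
null_test_graph <- function() {
  data.frame(
    pop     = c("root", "O", "anc", "L", "R1", "R2", "R3", "R4"),
    parent1 = c(NA, "root", "root", "anc", "anc", "anc", "root", "anc"),
    parent2 = NA, alpha = NA,
    drift   = c(0, 0.1, 0.02, 0.02, 0.03, 0.03, 0.08, 0.05),
    stringsAsFactors = FALSE)
}
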