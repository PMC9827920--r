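test_that("allele-frequency draws follow the configured model", {
  # explicit vector passes through untouched
  p <- c(0.2, 0.5, 0.9)
  cfg <- sim_config(freqs = p, seed = 1)
  expect_identical(draw_allele_frequencies(cfg), p)

  # Beta(1,1): sample mean 0.5 +/- 0.005 at 1e5
  cfg <- sim_config(n_snps = 1e5, freq_beta = c(1, 1), seed = 3)
  draws <- draw_allele_frequencies(cfg)
  expect_lt(abs(mean(draws) - 0.5), 0.005)
  expect_true(all(draws > 0 & draws < 1))
  expect_identical(draw_allele_frequencies(cfg), draws)  # seeded determinism

  # Beta(0.5,0.5) is U-shaped: edges heavier than the centre
  cfg <- sim_config(n_snps = 1e5, freq_beta = c(0.5, 0.5), seed = 4)
  d <- draw_allele_frequencies(cfg)
  expect_lt(mean(d > 0.4 & d < 0.6), mean(d < 0.2 | d > 0.8))

  expect_error(sim_config(freq_beta = c(0, 1)), "Beta")
  expect_error(sim_config(base_error = 0.5), "base_error")
  expect_error(sim_config(missingness = 1), "missingness")
})

test_that("pedigree genotype simulation obeys Mendelian transmission and truth identities", {
  # hom-alt x hom-ref forces heterozygous children
  spec <- pedigree_spec(id = c("p1", "p2", "c1", "c2"),
                        sex = c("M", "F", "M", "F"),
                        father = c(NA, NA, "p1", "p1"),
                        mother = c(NA, NA, "p2", "p2"),
                        generation = c(1, 1, 2, 2))
  sim <- simulate_pedigree_genotypes(spec, freqs = rep(0.5, 200), seed = 2)
  g <- sim$genotypes$calls
  forced <- g["p1", ] == 2L & g["p2", ] == 0L
  expect_true(any(forced))
  expect_true(all(g["c1", forced] == 1L))

  # full-sibling truth is exactly Mendel's table
  tr <- sim$truth$pairs
  fs <- tr[tr$id1 == "c1" & tr$id2 == "c2", ]
  expect_equal(c(fs$k0, fs$k1, fs$k2), c(0.25, 0.5, 0.25))

  # kappa = k1/4 + k2/2 for every simulated pair of the family pedigree
  fam <- family_test_pedigree()
  sim <- simulate_pedigree_genotypes(fam$spec, rep(0.5, 10), seed = 5)
  tr <- sim$truth$pairs
  expect_equal(tr$kappa, tr$k1 / 4 + tr$k2 / 2, tolerance = 1e-12)
  expect_equal(tr$k0 + tr$k1 + tr$k2, rep(1, nrow(tr)), tolerance = 1e-12)

  # single-recorded-parent member is rejected
  expect_error(pedigree_spec(id = c("a", "b"), sex = c("F", "M"),
                             father = c(NA, NA), mother = c(NA, "a"),
                             generation = c(1, 2)),
               "one recorded parent")
})

test_that("uniparental haplogroups follow maternal and paternal chains", {
  fam <- family_test_pedigree()
  spec <- fam$spec
  for (i in seq_len(nrow(spec))) {
    if (!is.na(spec$mother[i])) {
      expect_identical(spec$mt_hg[i], spec$mt_hg[match(spec$mother[i], spec$id)])
    }
    if (!is.na(spec$father[i]) && spec$sex[i] == "M") {
      expect_identical(spec$y_hg[i], spec$y_hg[match(spec$father[i], spec$id)])
    }
  }
  expect_true(all(is.na(spec$y_hg[spec$sex == "F"])))
  # the maternal uncle analogue shares mt with the children but not Y
  expect_identical(spec$mt_hg[spec$id == "UNC"], spec$mt_hg[spec$id == "SON"])
  expect_false(identical(spec$y_hg[spec$id == "UNC"], spec$y_hg[spec$id == "SON"]))
  # the paternal relative shares Y with the father
  expect_identical(spec$y_hg[spec$id == "REL"], spec$y_hg[spec$id == "FTH"])
})

test_that("parent-offspring PMR matches the (1 - kappa) b closed form", {
  # at freq 0.5 the unrelated baseline is b = 0.5, so a parent-offspring
  # pair has expected PMR (1 - 1/4) * 0.5 = 0.375
  n <- 1e5
  spec <- pedigree_spec(id = c("p1", "p2", "c1"), sex = c("M", "F", "M"),
                        father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
                        generation = c(1, 1, 2))
  sim <- simulate_pedigree_genotypes(spec, rep(0.5, n), seed = 11)
  hap <- pseudo_haploidize(sim$genotypes, seed = 12)
  est <- pairwise_mismatch_rate(hap, "p1", "c1", autosomes_only = FALSE)
  expect_lt(abs(est$pmr - 0.375), 3 * sqrt(0.375 * 0.625 / n))
  # implied kappa estimate
  kappa_hat <- 1 - est$pmr / 0.5
  expect_lt(abs(kappa_hat - 0.25), 3 * est$se / 0.5)
})

test_that("read simulation reproduces depth, error and contamination models", {
  cfg0 <- sim_config(n_snps = 100, mean_depth = 0, seed = 1)
  g <- genotype_matrix(matrix(1L, 2, 100), "diploid", c("a", "b"))
  rc <- simulate_reads(g, cfg0)
  expect_true(all(rc$ref + rc$alt == 0L))

  # heterozygote, no error/contamination: alt fraction 0.5
  n <- 2e4
  cfg <- sim_config(n_snps = n, mean_depth = 10, base_error = 1e-9,
                    seed = 2)
  g <- genotype_matrix(matrix(1L, 1, n), "diploid", "a")
  rc <- simulate_reads(g, cfg)
  tot <- sum(rc$ref + rc$alt)
  frac <- sum(rc$alt) / tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / tot))

  # hom-ref with 1% error: alt fraction ~= 0.01
  cfg <- sim_config(n_snps = n, mean_depth = 50, base_error = 0.01, seed = 3)
  g <- genotype_matrix(matrix(0L, 1, n), "diploid", "a")
  rc <- simulate_reads(g, cfg)
  tot <- sum(rc$ref + rc$alt)
  frac <- sum(rc$alt) / tot
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / tot))

  # contamination from an alt-fixed source: hom-ref individual reads alt at
  # the contamination rate
  cfg <- sim_config(n_snps = n, mean_depth = 10, base_error = 1e-9,
                    contamination_rate = 0.1, contaminant_freqs = 1,
                    seed = 4)
  rc <- simulate_reads(g, cfg)
  tot <- sum(rc$ref + rc$alt)
  frac <- sum(rc$alt) / tot
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / tot))

  # missingness forces extra zero-depth sites
  cfg <- sim_config(n_snps = n, mean_depth = 10, missingness = 0.4, seed = 5)
  rc <- simulate_reads(g, cfg)
  expect_lt(abs(mean(rc$ref + rc$alt == 0) - 0.4), 0.02)
})

test_that("admixture-graph frequencies honour mixing weights and drift", {
  cfg <- sim_config(n_snps = 5000, seed = 6)
  # zero drift, alpha = 1: admixed equals source1 exactly
  graph <- data.frame(pop = c("r", "s1", "s2", "adm"),
                      parent1 = c(NA, "r", "r", "s1"),
                      parent2 = c(NA, NA, NA, "s2"),
                      alpha = c(NA, NA, NA, 1),
                      drift = c(0, 0, 0.05, 0), stringsAsFactors = FALSE)
  fr <- simulate_admixture_freqs(graph, cfg)
  expect_identical(fr[, "adm"], fr[, "s1"])

  # alpha = 0.5, zero post-admixture drift: exact arithmetic mean
  graph$alpha[4] <- 0.5
  graph$drift[2] <- 0.05
  fr <- simulate_admixture_freqs(graph, cfg)
  expect_equal(fr[, "adm"], (fr[, "s1"] + fr[, "s2"]) / 2, tolerance = 1e-12)

  expect_error(simulate_admixture_freqs(transform(graph, alpha = 1.5), cfg),
               "alpha")
  expect_error(simulate_admixture_freqs(transform(graph, drift = -1), cfg),
               "drift")
})

test_that("f4-ratio on simulated admixture recovers the mixing proportion", {
  # f4(S1, S2; T, S2) / f4(S1, S2; S1, S2) = alpha
  alpha <- 0.3
  n <- 1e5
  graph <- admixture_test_graph(alpha)
  blk <- assign_jackknife_blocks(synthetic_snp_panel(n))
  # the 2-s.e. interval is a ~95% property, so allow one excursion across
  # independent replicates
  hits <- vapply(1:5, function(sd) {
    cfg <- sim_config(n_snps = n, seed = sd + 7)
    fr <- simulate_admixture_freqs(graph, cfg)
    num <- (fr[, "S1"] - fr[, "S2"]) * (fr[, "T"] - fr[, "S2"])
    den <- (fr[, "S1"] - fr[, "S2"]) * (fr[, "S1"] - fr[, "S2"])
    jk <- block_jackknife(num, blk, den)
    abs(jk$estimate - alpha) < 2 * jk$se
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("individual sampling from frequencies is HWE, unbiased and seeded", {
  p <- rep(1, 50)
  samp <- sample_individuals_from_freqs(p, 3, seed = 1)
  expect_true(all(samp$genotypes$calls == 2L))

  n <- 2e4
  cfg <- sim_config(n_snps = n, seed = 9)
  p <- draw_allele_frequencies(cfg)
  samp <- sample_individuals_from_freqs(matrix(p, dimnames = list(NULL, "a")),
                                        50, seed = 2)
  phat <- colMeans(samp$genotypes$calls) / 2
  # mean deviation across sites under 3 s.e. of the mean deviation
  dev <- mean(phat - p)
  se <- sqrt(mean(p * (1 - p) / (2 * 50)) / n)
  expect_lt(abs(dev), 3 * se)

  again <- sample_individuals_from_freqs(matrix(p, dimnames = list(NULL, "a")),
                                         50, seed = 2)
  expect_identical(again$genotypes$calls, samp$genotypes$calls)
  expect_error(sample_individuals_from_freqs(p, 0, seed = 1), "n_per_pop")
})
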