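test_that("pairwise mismatch rate counts overlap and mismatches exactly", {
  g <- genotype_matrix(rbind(A = c(0L, 0L, 1L, 1L), B = c(0L, 1L, 1L, 0L)),
                       "haploid")
  est <- pairwise_mismatch_rate(g, "A", "B", autosomes_only = FALSE)
  expect_equal(est$n_overlap, 4L)
  expect_equal(est$pmr, 0.5)

  # sites missing in either individual are excluded
  g <- genotype_matrix(rbind(A = c(0L, NA, 1L), B = c(0L, 1L, NA)), "haploid")
  est <- pairwise_mismatch_rate(g, "A", "B", autosomes_only = FALSE)
  expect_equal(est$n_overlap, 1L)
  expect_equal(est$pmr, 0)

  # zero overlap errors, naming the pair
  g <- genotype_matrix(rbind(A = c(0L, NA), B = c(NA, 1L)), "haploid")
  expect_error(pairwise_mismatch_rate(g, "A", "B", autosomes_only = FALSE),
               "A-B")

  # against a naive per-site loop on random data
  set.seed(77)
  g <- random_genotypes(2, 1e4, "haploid", missing_rate = 0.3, seed = 77)
  est <- pairwise_mismatch_rate(g, "ind01", "ind02", autosomes_only = FALSE)
  a <- g$calls[1, ]; b <- g$calls[2, ]
  n_o <- 0L; n_m <- 0L
  for (s in seq_along(a)) {
    if (!is.na(a[s]) && !is.na(b[s])) {
      n_o <- n_o + 1L
      if (a[s] != b[s]) n_m <- n_m + 1L
    }
  }
  expect_equal(est$n_overlap, n_o)
  expect_equal(est$n_mismatch, n_m)

  # autosome filtering drops X-chromosome sites
  panel <- snp_panel(c("a1", "a2", "x1"), c("1", "1", "X"),
                     c(100L, 200L, 100L))
  g <- genotype_matrix(rbind(A = c(0L, 1L, 1L), B = c(1L, 1L, 0L)), "haploid")
  est <- pairwise_mismatch_rate(g, "A", "B", panel = panel)
  expect_equal(est$n_overlap, 2L)
  expect_equal(est$n_mismatch, 1L)
})

test_that("baseline mismatch rate is the panel median with dispersion summary", {
  # single pair: baseline equals that pair's PMR exactly
  g <- genotype_matrix(rbind(A = c(0L, 0L, 1L, 1L), B = c(0L, 1L, 1L, 0L)),
                       "haploid")
  b <- background_pmr(g, autosomes_only = FALSE)
  expect_equal(b$b, 0.5)
  expect_error(background_pmr(genotype_matrix(matrix(0L, 1, 4), "haploid")),
               ">= 2")

  # unrelated panel at freq 0.5: b ~= 0.5
  n <- 2e4
  samp <- sample_individuals_from_freqs(rep(0.5, n), 10, seed = 3)
  hap <- pseudo_haploidize(samp$genotypes, seed = 4)
  b <- background_pmr(hap, autosomes_only = FALSE)
  expect_lt(abs(b$b - 0.5), 3 * sqrt(0.25 / n))

  # two copies of one genotype behave like an identical pair: b ~= b0/2
  dup <- genotype_matrix(samp$genotypes$calls[c(1, 1), ], "diploid",
                         c("c1", "c2"))
  hap2 <- pseudo_haploidize(dup, seed = 5)
  b2 <- background_pmr(hap2, autosomes_only = FALSE)
  expect_lt(abs(b2$b - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("degree classification uses midpoint boundaries with distant-ward ties", {
  mk <- function(npmr) list(id1 = "a", id2 = "b", pmr = npmr, n_overlap = 20000L)
  cls <- function(npmr) classify_degree(mk(npmr), baseline = 1)$degree
  expect_identical(cls(0.74), "first")
  expect_identical(cls(0.52), "identical")
  expect_identical(cls(0.88), "second")
  expect_identical(cls(0.94), "third")
  expect_identical(cls(0.99), "unrelated")
  # exact boundaries tie toward the more distant degree
  expect_identical(cls(0.625), "first")
  expect_identical(cls(0.8125), "second")
  expect_identical(cls(0.90625), "third")
  expect_identical(cls(0.96875), "unrelated")
  expect_error(classify_degree(mk(0.8), baseline = 0), "baseline")
  expect_true(classify_degree(mk(0.8), 1, min_overlap = 50000)$low_confidence)
})

test_that("degree classification recovers simulated relationships at 1e5 SNPs", {
  # parent-offspring, half-sib, first-cousin and unrelated pairs across
  # seeded replicates; margins at 1e5 overlapping SNPs are ~10 sigma
  n <- 1e5
  freqs <- rep(0.5, n)
  spec <- pedigree_spec(
    id = c("gp1", "gp2", "f1", "f2", "m1", "m2", "po", "hs", "fc", "un"),
    sex = c("M", "F", "M", "M", "F", "F", "M", "M", "M", "F"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "f1", "f1", "f2", NA),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "m1", "m2", "m2", NA),
    generation = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3))
  ok <- 0L
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    sim <- simulate_pedigree_genotypes(spec, freqs, seed = 100 + r)
    hap <- pseudo_haploidize(sim$genotypes, seed = 200 + r)
    got <- vapply(list(c("f1", "po"), c("po", "hs"), c("po", "fc"),
                       c("po", "un")), function(pr) {
      est <- pairwise_mismatch_rate(hap, pr[1], pr[2], autosomes_only = FALSE)
      classify_degree(est, 0.5)$degree
    }, character(1))
    if (identical(got, c("first", "second", "third", "unrelated"))) ok <- ok + 1L
  }
  expect_gte(ok, n_rep - 1L)
})

test_that("genotype likelihoods match the closed-form binomial", {
  gl <- genotype_likelihoods(0L, 0L, 0.01)
  expect_equal(as.vector(gl), rep(1 / 3, 3))

  gl <- genotype_likelihoods(5L, 5L, 0.01)
  expect_identical(which.max(gl[1, ]), c(g1 = 2L))

  set.seed(9)
  ref <- rpois(200, 3); alt <- rpois(200, 3)
  gl <- genotype_likelihoods(ref, alt, 0.02)
  n <- ref + alt
  for (g in 0:2) {
    e <- c(0.02, 0.5, 0.98)[g + 1]
    raw <- dbinom(alt, n, e)
    tot <- dbinom(alt, n, 0.02) + dbinom(alt, n, 0.5) + dbinom(alt, n, 0.98)
    expected <- ifelse(n == 0, 1 / 3, raw / tot)
    expect_equal(gl[, g + 1], unname(expected), tolerance = 1e-12)
  }
  expect_error(genotype_likelihoods(-1L, 0L, 0.01), "counts")
  expect_error(genotype_likelihoods(1L, 0L, 0.7), "base_error")
})

test_that("IBD-coefficient EM separates identical, parent-offspring and unrelated pairs", {
  n <- 5e4
  cfg <- sim_config(n_snps = n, mean_depth = 5, base_error = 0.01, seed = 20)
  p <- draw_allele_frequencies(cfg)
  spec <- pedigree_spec(id = c("p1", "p2", "c1"), sex = c("M", "F", "M"),
                        father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
                        generation = c(1, 1, 2))
  sim <- simulate_pedigree_genotypes(spec, p, seed = 21)
  rc1 <- simulate_reads(sim$genotypes, cfg, seed = 22)
  rc2 <- simulate_reads(sim$genotypes, cfg, seed = 23)
  gl <- function(rc, id) genotype_likelihoods(rc$ref[id, ], rc$alt[id, ], 0.01)

  # same genotypes, independent reads: k2 >= 0.95
  self <- suppressWarnings(
    estimate_ibd_coefficients(gl(rc1, "c1"), gl(rc2, "c1"), p))
  expect_gte(self$k2, 0.95)

  # parent-offspring: k0 small, k1 dominant
  po <- suppressWarnings(
    estimate_ibd_coefficients(gl(rc1, "p1"), gl(rc1, "c1"), p))
  expect_lte(po$k0, 0.05)
  expect_gte(po$k1, 0.9)

  # unrelated founders: k0 >= 0.9
  un <- suppressWarnings(
    estimate_ibd_coefficients(gl(rc1, "p1"), gl(rc1, "p2"), p))
  expect_gte(un$k0, 0.9)

  # simplex constraint and monotone log-likelihood
  for (res in list(self, po, un)) {
    expect_lt(abs(res$k0 + res$k1 + res$k2 - 1), 1e-9)
    expect_true(all(diff(res$ll_trace) > -1e-8))
  }
  expect_error(estimate_ibd_coefficients(matrix(1 / 3, 10, 3),
                                         matrix(1 / 3, 10, 3),
                                         rep(0.5, 10)),
               "informative sites")
})

test_that("first-degree disambiguation applies the k0/k2 rule", {
  expect_identical(disambiguate_first_degree(list(k0 = 0.01, k1 = 0.97,
                                                  k2 = 0.02))$type,
                   "parent_offspring")
  expect_identical(disambiguate_first_degree(list(k0 = 0.25, k1 = 0.5,
                                                  k2 = 0.25))$type,
                   "full_sibling")
  expect_identical(disambiguate_first_degree(list(k0 = 0.07, k1 = 0.85,
                                                  k2 = 0.08))$type,
                   "undetermined")
})

test_that("relative pruning finds an exact maximum unrelated subset", {
  # fully unrelated: everyone retained
  prs <- utils::combn(letters[1:4], 2)
  deg <- data.frame(id1 = prs[1, ], id2 = prs[2, ], degree = "unrelated",
                    stringsAsFactors = FALSE)
  expect_identical(prune_relatives(deg), letters[1:4])

  # the family pedigree: maximum unrelated set has size 3
  kept <- prune_relatives(family_degrees(),
                          coverage = c(FTH = 5, MTH = 1, SON = 2, DAU = 2,
                                       UNC = 4, REL = 3))
  expect_identical(kept, sort(c("FTH", "REL", "UNC")))

  # random graphs against a brute-force oracle for the set size
  set.seed(5)
  for (r in 1:10) {
    n <- sample(4:9, 1)
    ids <- sprintf("i%02d", seq_len(n))
    prs <- utils::combn(ids, 2)
    close <- runif(ncol(prs)) < 0.35
    deg <- data.frame(id1 = prs[1, ], id2 = prs[2, ],
                      degree = ifelse(close, "second", "unrelated"),
                      stringsAsFactors = FALSE)
    kept <- prune_relatives(deg)
    # oracle: enumerate all subsets
    best <- 0L
    adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (k in which(close)) adj[prs[1, k], prs[2, k]] <-
        adj[prs[2, k], prs[1, k]] <- TRUE
    for (mask in 0:(2^n - 1)) {
      mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (!any(adj[mem, mem])) best <- max(best, length(mem))
    }
    expect_identical(length(kept), best)
    # no retained pair is closely related
    expect_false(any(adj[kept, kept]))
  }
})
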