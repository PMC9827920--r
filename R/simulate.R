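#' Simulation configuration
#'
#' Bundles and validates the parameters of the low-coverage read simulator
#' and the allele-frequency model.
#'
#' @param n_snps number of unlinked SNPs (>= 1).
#' @param freq_beta length-2 Beta(a, b) parameters for founder allele
#'   frequencies, or `NULL` when `freqs` is given.
#' @param freqs optional explicit frequency vector (overrides `freq_beta`).
#' @param mean_depth mean Poisson sequencing depth per site (>= 0).
#' @param base_error per-read allele flip probability, in `[0, 0.5)`.
#' @param contamination_rate fraction of reads drawn from the contaminant
#'   source, in `[0, 1)`.
#' @param contaminant_freqs allele-frequency vector of the contaminant
#'   source (recycled to `n_snps`); defaults to 0.5.
#' @param missingness extra fraction of sites forced to zero depth, `[0, 1)`.
#' @param seed master integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 1e5, freq_beta = c(1, 1), freqs = NULL,
                       mean_depth = 1, base_error = 0.01,
                       contamination_rate = 0, contaminant_freqs = 0.5,
                       missingness = 0, seed = 1) {
  if (n_snps < 1) stop("sim_config: n_snps must be >= 1", call. = FALSE)
  if (!is.null(freqs)) {
    if (any(freqs <= 0 | freqs >= 1)) {
      stop("sim_config: explicit frequencies must lie in (0,1)", call. = FALSE)
    }
    n_snps <- length(freqs)
  } else if (any(freq_beta <= 0) || length(freq_beta) != 2) {
    stop("sim_config: degenerate Beta parameters", call. = FALSE)
  }
  if (mean_depth < 0) stop("sim_config: mean_depth must be >= 0", call. = FALSE)
  if (base_error < 0 || base_error >= 0.5) {
    stop("sim_config: base_error must be in [0, 0.5)", call. = FALSE)
  }
  if (contamination_rate < 0 || contamination_rate >= 1) {
    stop("sim_config: contamination_rate must be in [0, 1)", call. = FALSE)
  }
  if (missingness < 0 || missingness >= 1) {
    stop("sim_config: missingness must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), freq_beta = freq_beta,
                 freqs = freqs, mean_depth = mean_depth,
                 base_error = base_error,
                 contamination_rate = contamination_rate,
                 contaminant_freqs = contaminant_freqs,
                 missingness = missingness, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw founder allele frequencies
#'
#' Explicit frequencies pass through unchanged; otherwise frequencies are
#' drawn from the configured Beta distribution (clamped away from 0/1 so
#' that downstream likelihoods are proper). Deterministic given the config
#' seed; uses sub-stream 1 of the master seed.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_snps` with values in (0, 1).
#' @export
draw_allele_frequencies <- function(config) {
  if (!is.null(config$freqs)) return(config$freqs)
  with_seed(derive_seed(config$seed, 1L), {
    p <- stats::rbeta(config$n_snps, config$freq_beta[1], config$freq_beta[2])
    pmin(pmax(p, 1e-6), 1 - 1e-6)
  })
}

#' Pedigree specification for simulation
#'
#' One row per member: `id`, `sex` ("M"/"F"), `father`, `mother` (both `NA`
#' for founders -- a member has exactly 0 or 2 recorded parents),
#' `generation` (founders precede children), and founder uniparental
#' haplogroup labels `mt_hg`, `y_hg` (descendant labels are derived:
#' mitochondrial down the maternal line, Y down the paternal line, males
#' only).
#'
#' @param id,sex,father,mother,generation,mt_hg,y_hg per-member vectors.
#' @return data frame of class `pedigree_spec`.
#' @export
pedigree_spec <- function(id, sex, father = NA, mother = NA, generation = 1,
                          mt_hg = NA, y_hg = NA) {
  n <- length(id)
  spec <- data.frame(id = as.character(id), sex = as.character(sex),
                     father = rep_len(as.character(father), n),
                     mother = rep_len(as.character(mother), n),
                     generation = rep_len(as.integer(generation), n),
                     mt_hg = rep_len(as.character(mt_hg), n),
                     y_hg = rep_len(as.character(y_hg), n),
                     stringsAsFactors = FALSE)
  spec$father[spec$father %in% c("0", "")] <- NA
  spec$mother[spec$mother %in% c("0", "")] <- NA
  one_parent <- xor(is.na(spec$father), is.na(spec$mother))
  if (any(one_parent)) {
    stop(sprintf("pedigree_spec: member(s) with exactly one recorded parent: %s",
                 paste(spec$id[one_parent], collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(n)) {
    for (par in c(spec$father[i], spec$mother[i])) {
      if (!is.na(par)) {
        j <- match(par, spec$id)
        if (is.na(j)) stop(sprintf("pedigree_spec: unknown parent '%s'", par),
                           call. = FALSE)
        if (spec$generation[j] >= spec$generation[i]) {
          stop(sprintf("pedigree_spec: parent '%s' does not precede child '%s'",
                       par, spec$id[i]), call. = FALSE)
        }
      }
    }
  }
  # parent sexes
  fa <- spec$sex[match(spec$father, spec$id)]
  mo <- spec$sex[match(spec$mother, spec$id)]
  if (any(fa == "F", na.rm = TRUE) || any(mo == "M", na.rm = TRUE)) {
    stop("pedigree_spec: father must be male and mother female", call. = FALSE)
  }
  # default founder haplogroup labels
  founder <- is.na(spec$father)
  need_mt <- founder & is.na(spec$mt_hg)
  spec$mt_hg[need_mt] <- paste0("mt_", spec$id[need_mt])
  need_y <- founder & spec$sex == "M" & is.na(spec$y_hg)
  spec$y_hg[need_y] <- paste0("Y_", spec$id[need_y])
  # derive descendant haplogroups in generation order
  for (i in order(spec$generation)) {
    if (!is.na(spec$mother[i])) {
      spec$mt_hg[i] <- spec$mt_hg[match(spec$mother[i], spec$id)]
    }
    if (!is.na(spec$father[i]) && spec$sex[i] == "M") {
      spec$y_hg[i] <- spec$y_hg[match(spec$father[i], spec$id)]
    }
  }
  spec$y_hg[spec$sex == "F"] <- NA
  class(spec) <- c("pedigree_spec", "data.frame")
  spec
}

#' @rdname pedigree_spec
#' @param path file to read/write (whitespace-separated, one member per
#'   line: id sex father mother generation mt_hg y_hg; `0` for no parent).
#' @export
read_pedigree_spec <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "0"))
  pedigree_spec(tab$id, tab$sex, tab$father, tab$mother, tab$generation,
                tab$mt_hg, tab$y_hg)
}

#' @rdname pedigree_spec
#' @param spec a `pedigree_spec`.
#' @export
write_pedigree_spec <- function(spec, path) {
  out <- spec
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate diploid genotypes down a pedigree
#'
#' Founders are drawn under Hardy-Weinberg equilibrium (`Binomial(2, p)` per
#' site); each child receives one allele from each parent, transmitted
#' independently per SNP (sites are unlinked). Returns the genotypes and a
#' truth set with pedigree-derived kinship coefficients per pair
#' (`kappa = k1/4 + k2/2`) and derived uniparental haplogroups.
#'
#' @param spec a [pedigree_spec()].
#' @param freqs founder allele-frequency vector.
#' @param seed integer seed.
#' @return list with `genotypes` (diploid [genotype_matrix()]) and `truth`
#'   (list with `pairs` data frame: id1, id2, kappa, k0, k1, k2; and
#'   `haplogroups` data frame).
#' @export
simulate_pedigree_genotypes <- function(spec, freqs, seed) {
  n_snps <- length(freqs)
  ids <- spec$id
  with_seed(seed, {
    geno <- matrix(NA_integer_, nrow = length(ids), ncol = n_snps,
                   dimnames = list(ids, NULL))
    for (i in order(spec$generation)) {
      if (is.na(spec$father[i])) {
        geno[i, ] <- stats::rbinom(n_snps, 2L, freqs)
      } else {
        gf <- geno[match(spec$father[i], ids), ]
        gm <- geno[match(spec$mother[i], ids), ]
        geno[i, ] <- stats::rbinom(n_snps, 1L, gf / 2) +
          stats::rbinom(n_snps, 1L, gm / 2)
      }
    }
    ped <- ped_nodes(ids, spec$father, spec$mother, spec$sex)
    pairs <- utils::combn(ids, 2)
    truth <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                        stringsAsFactors = FALSE)
    ks <- t(apply(pairs, 2, function(pr) {
      k <- ped_relatedness(ped, pr[1], pr[2])
      c(k$kappa, k$k0, k$k1, k$k2)
    }))
    truth$kappa <- ks[, 1]; truth$k0 <- ks[, 2]
    truth$k1 <- ks[, 3]; truth$k2 <- ks[, 4]
    list(genotypes = genotype_matrix(geno, "diploid", ids),
         truth = list(pairs = truth,
                      haplogroups = spec[, c("id", "sex", "mt_hg", "y_hg")]))
  })
}

#' Simulate low-coverage read counts
#'
#' Per site and individual, sequencing depth is Poisson with the configured
#' mean; a fraction `missingness` of sites is forced to zero depth. Each
#' read derives from the contaminant frequency with probability
#' `contamination_rate`, otherwise from the individual's genotype, and flips
#' allele with probability `base_error`. Reads are conditionally independent
#' given the site, so the alt count is binomial with per-site success
#' probability `(1-c)*eadj(g/2) + c*eadj(q)` where
#' `eadj(p) = p(1-e) + (1-p)e`.
#'
#' @param genotypes diploid [genotype_matrix()].
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to sub-stream 2 of the config seed).
#' @return list of class `read_counts` with integer matrices `ref` and
#'   `alt` (individuals x SNPs).
#' @export
simulate_reads <- function(genotypes, config, seed = derive_seed(config$seed, 2L)) {
  g <- genotypes$calls
  n <- length(g)
  with_seed(seed, {
    depth <- matrix(stats::rpois(n, config$mean_depth), nrow = nrow(g))
    if (config$missingness > 0) {
      depth[matrix(stats::runif(n) < config$missingness, nrow = nrow(g))] <- 0L
    }
    depth[is.na(g)] <- 0L
    q <- matrix(rep(rep_len(config$contaminant_freqs, ncol(g)),
                    each = nrow(g)), nrow = nrow(g))
    e <- config$base_error
    eadj <- function(p) p * (1 - e) + (1 - p) * e
    p_alt <- (1 - config$contamination_rate) * eadj(g / 2) +
      config$contamination_rate * eadj(q)
    p_alt[is.na(p_alt)] <- 0
    alt <- matrix(stats::rbinom(n, depth, p_alt), nrow = nrow(g))
    ref <- depth - alt
    rownames(ref) <- rownames(alt) <- genotypes$individual_ids
    structure(list(ref = ref, alt = alt), class = "read_counts")
  })
}

#' Simulate allele frequencies down an admixture graph
#'
#' Populations are listed in topological order. A root population draws its
#' frequencies from the config frequency model; a one-parent population
#' perturbs its parent's frequency `p` with a Normal deviate of variance
#' `p(1-p)*drift` (Balding-Nichols-style Brownian drift), truncated to
#' `[0, 1]`; a two-parent (admixed) population starts from
#' `alpha*p1 + (1-alpha)*p2` and then applies its own drift.
#'
#' @param graph data frame with columns `pop`, `parent1`, `parent2`
#'   (`NA` when absent), `alpha` (weight on `parent1`; `NA` for
#'   non-admixed) and `drift` (>= 0), in topological order with the root
#'   first.
#' @param config a [sim_config()] (frequency model and SNP count).
#' @param seed integer seed (defaults to sub-stream 3 of the config seed).
#' @return numeric matrix `n_snps x n_pops` with populations as columns.
#' @export
simulate_admixture_freqs <- function(graph, config,
                                     seed = derive_seed(config$seed, 3L)) {
  if (any(graph$drift < 0, na.rm = TRUE)) {
    stop("simulate_admixture_freqs: drift must be >= 0", call. = FALSE)
  }
  if (any(graph$alpha < 0 | graph$alpha > 1, na.rm = TRUE)) {
    stop("simulate_admixture_freqs: alpha must lie in [0, 1]", call. = FALSE)
  }
  root <- draw_allele_frequencies(config)
  n <- length(root)
  freqs <- matrix(NA_real_, nrow = n, ncol = nrow(graph),
                  dimnames = list(NULL, graph$pop))
  with_seed(seed, {
    for (i in seq_len(nrow(graph))) {
      p <- if (is.na(graph$parent1[i])) {
        root
      } else if (is.na(graph$parent2[i])) {
        freqs[, graph$parent1[i]]
      } else {
        graph$alpha[i] * freqs[, graph$parent1[i]] +
          (1 - graph$alpha[i]) * freqs[, graph$parent2[i]]
      }
      d <- graph$drift[i]
      if (d > 0) {
        p <- p + stats::rnorm(n, 0, sqrt(p * (1 - p) * d))
        p <- pmin(pmax(p, 0), 1)
      }
      freqs[, i] <- p
    }
  })
  freqs
}

#' Sample diploid individuals from population allele frequencies
#'
#' Genotypes are `Binomial(2, p)` per site under HWE; deterministic given
#' the seed.
#'
#' @param freqs matrix `n_snps x n_pops` (or a single frequency vector).
#' @param n_per_pop integer count of individuals per population (recycled).
#' @param seed integer seed.
#' @return list with `genotypes` (diploid [genotype_matrix()]) and
#'   `populations` (character label per individual).
#' @export
sample_individuals_from_freqs <- function(freqs, n_per_pop, seed) {
  if (is.vector(freqs)) freqs <- matrix(freqs, ncol = 1,
                                        dimnames = list(NULL, "pop1"))
  if (any(n_per_pop < 1)) {
    stop("sample_individuals_from_freqs: n_per_pop must be >= 1", call. = FALSE)
  }
  pops <- colnames(freqs)
  if (is.null(pops)) pops <- sprintf("pop%d", seq_len(ncol(freqs)))
  n_per_pop <- rep_len(as.integer(n_per_pop), ncol(freqs))
  with_seed(seed, {
    rows <- list(); labels <- character(0); ids <- character(0)
    for (j in seq_along(pops)) {
      g <- matrix(stats::rbinom(n_per_pop[j] * nrow(freqs), 2L,
                                rep(freqs[, j], each = n_per_pop[j])),
                  nrow = n_per_pop[j])
      rows[[j]] <- g
      labels <- c(labels, rep(pops[j], n_per_pop[j]))
      ids <- c(ids, sprintf("%s_%d", pops[j], seq_len(n_per_pop[j])))
    }
    calls <- do.call(rbind, rows)
    rownames(calls) <- ids
    list(genotypes = genotype_matrix(calls, "diploid", ids),
         populations = labels)
  })
}

#' A synthetic SNP panel with evenly spaced jackknife-ready positions
#'
#' SNPs are spread over 22 pseudo-chromosomes with genetic positions evenly
#' spaced at 0.01 cM and physical positions at 10 kb, so that 5 cM
#' block-jackknife windows are well defined.
#'
#' @param n_snps total number of SNPs.
#' @return a [snp_panel()].
#' @export
synthetic_snp_panel <- function(n_snps) {
  chrom <- rep(as.character(1:22), length.out = n_snps)
  chrom <- sort(as.integer(chrom))
  idx <- unlist(lapply(table(chrom), seq_len), use.names = FALSE)
  snp_panel(sprintf("snp%07d", seq_len(n_snps)), as.character(chrom),
            physical_position = idx * 10000L,
            genetic_position = idx * 0.01)
}

#' An extended-family test pedigree
#'
#' Builds the pedigree used throughout the package's validation: a couple
#' (`FTH`, `MTH`) with two children (`SON`, adult male; `DAU`, subadult
#' female); `UNC`, a son of the mother by another partner (so a first-degree
#' relative of the mother and second-degree to both children, unrelated to
#' the father); and `REL`, a paternal half-uncle of the father (third
#' degree to the father, sharing his Y haplogroup). Six members are marked
#' observed; the remaining six are unsampled connectors.
#'
#' @return list with `spec` (full [pedigree_spec()]), `observed` (ids of the
#'   six sampled members) and `meta` (an [individual_meta()] for them).
#' @export
family_test_pedigree <- function() {
  spec <- pedigree_spec(
    id       = c("GF",  "GM", "TM", "PM", "MTH", "UF", "PF", "REL", "FTH", "UNC", "SON", "DAU"),
    sex      = c("M",   "F",  "F",  "F",  "F",   "M",  "M",  "M",   "M",   "M",   "M",   "F"),
    father   = c(NA,    NA,   NA,   NA,   NA,    NA,   "GF", "GF",  "PF",  "UF",  "FTH", "FTH"),
    mother   = c(NA,    NA,   NA,   NA,   NA,    NA,   "GM", "TM",  "PM",  "MTH", "MTH", "MTH"),
    generation = c(1,   1,    1,    2,    3,     3,    2,    2,     3,     4,     4,     4)
  )
  observed <- c("FTH", "MTH", "SON", "DAU", "UNC", "REL")
  hg <- spec[match(observed, spec$id), ]
  meta <- individual_meta(
    id = observed,
    genetic_sex = ifelse(hg$sex == "M", "XY", "XX"),
    age_class = c("adult", "adult", "adult", "subadult", "adult", "adult"),
    mt_haplogroup = hg$mt_hg,
    y_haplogroup = ifelse(is.na(hg$y_hg), "unknown", hg$y_hg)
  )
  list(spec = spec, observed = observed, meta = meta)
}
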