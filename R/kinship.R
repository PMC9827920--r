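#' Pairwise mismatch rate (PMR)
#'
#' Fraction of sites, among those called in both individuals, where the two
#' single sampled alleles differ. Scales as `(1 - kappa) * b` where `kappa`
#' is the kinship coefficient and `b` the mismatch rate of unrelated pairs.
#' Autosomal sites only by default.
#'
#' @param genotypes haploid [genotype_matrix()].
#' @param id1,id2 individual ids.
#' @param panel optional [snp_panel()]; required when `autosomes_only`.
#' @param autosomes_only restrict to chromosomes "1".."22".
#' @return list of class `pmr_estimate` with `id1`, `id2`, `n_overlap`,
#'   `n_mismatch`, `pmr` and binomial `se`.
#' @export
pairwise_mismatch_rate <- function(genotypes, id1, id2, panel = NULL,
                                   autosomes_only = TRUE) {
  if (genotypes$ploidy != "haploid") {
    stop("pairwise_mismatch_rate: haploid calls required", call. = FALSE)
  }
  a <- genotypes$calls[match_individual(genotypes, id1), ]
  b <- genotypes$calls[match_individual(genotypes, id2), ]
  if (autosomes_only && !is.null(panel)) {
    keep <- is_autosome(panel$chromosome)
    a <- a[keep]; b <- b[keep]
  }
  both <- !is.na(a) & !is.na(b)
  n_overlap <- sum(both)
  if (n_overlap == 0) {
    stop(sprintf("no overlapping called sites for pair %s-%s", id1, id2),
         call. = FALSE)
  }
  n_mismatch <- sum(a[both] != b[both])
  pmr <- n_mismatch / n_overlap
  structure(list(id1 = id1, id2 = id2, n_overlap = n_overlap,
                 n_mismatch = n_mismatch, pmr = pmr,
                 se = sqrt(pmr * (1 - pmr) / n_overlap)),
            class = "pmr_estimate")
}

#' PMR for all pairs of a set of individuals
#'
#' @param genotypes haploid [genotype_matrix()].
#' @param ids individuals to pair (default all).
#' @inheritParams pairwise_mismatch_rate
#' @return data frame with one row per unordered pair.
#' @export
pmr_all_pairs <- function(genotypes, ids = genotypes$individual_ids,
                          panel = NULL, autosomes_only = TRUE) {
  prs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    est <- pairwise_mismatch_rate(genotypes, prs[1, k], prs[2, k], panel,
                                  autosomes_only)
    data.frame(id1 = est$id1, id2 = est$id2, n_overlap = est$n_overlap,
               n_mismatch = est$n_mismatch, pmr = est$pmr, se = est$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Baseline mismatch rate of an unrelated reference panel
#'
#' The baseline `b` is the median of all retained pairwise PMR values of a
#' reference panel of (presumed) unrelated individuals; the median is robust
#' to a few undetected relatives. Dispersion (min/max/IQR) is returned so
#' that panels contaminated by close relatives can be flagged.
#'
#' @param genotypes haploid [genotype_matrix()] of the reference panel.
#' @param exclude_pairs optional data frame `id1`, `id2` of pairs to drop.
#' @inheritParams pairwise_mismatch_rate
#' @return list of class `pmr_baseline`: `b`, `n_pairs`, `min`, `max`,
#'   `iqr`, and the full `pairs` table.
#' @export
background_pmr <- function(genotypes, exclude_pairs = NULL, panel = NULL,
                           autosomes_only = TRUE) {
  ids <- genotypes$individual_ids
  if (length(ids) < 2) {
    stop("background_pmr: need >= 2 reference individuals", call. = FALSE)
  }
  tab <- pmr_all_pairs(genotypes, ids, panel, autosomes_only)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tab <- tab[!key(tab$id1, tab$id2) %in%
                 key(exclude_pairs$id1, exclude_pairs$id2), ]
  }
  if (!nrow(tab)) stop("background_pmr: no pairs retained", call. = FALSE)
  structure(list(b = stats::median(tab$pmr), n_pairs = nrow(tab),
                 min = min(tab$pmr), max = max(tab$pmr),
                 iqr = stats::IQR(tab$pmr), pairs = tab),
            class = "pmr_baseline")
}

#' Classify relationship degree from a normalized PMR
#'
#' The expected PMR of a degree-k pair is `(1 - kappa_k) * b`, so the
#' expected normalized PMR (`pmr / b`) is `1 - 2^-(k+1)`: 0.5 for identical
#' genomes, 0.75 for first degree, 0.875 second, 0.9375 third, 1 for
#' unrelated. A pair is assigned to the class whose expectation is nearest,
#' i.e. with boundaries at the midpoints 0.625, 0.8125, 0.90625, 0.96875;
#' values above 0.96875 are unrelated and exact boundary ties break toward
#' the more distant degree (conservative against over-claiming kinship).
#' Calls with fewer than `min_overlap` overlapping SNPs are flagged
#' low-confidence.
#'
#' @param pmr a `pmr_estimate` from [pairwise_mismatch_rate()] (or a list
#'   with `pmr` and `n_overlap`).
#' @param baseline positive baseline `b` (or a `pmr_baseline`).
#' @param min_overlap minimum overlapping SNPs for a confident call.
#' @return list of class `degree_call`: `normalized_pmr`, `degree`,
#'   `expected` (named expectation vector), `low_confidence`.
#' @export
classify_degree <- function(pmr, baseline, min_overlap = 10000) {
  b <- if (inherits(baseline, "pmr_baseline")) baseline$b else baseline
  if (!is.numeric(b) || b <= 0) {
    stop("classify_degree: baseline must be > 0", call. = FALSE)
  }
  npmr <- pmr$pmr / b
  labels <- c("identical", "first", "second", "third", "unrelated")
  bounds <- c(0.625, 0.8125, 0.90625, 0.96875)
  # boundary values fall in the upper interval (the more distant degree)
  idx <- findInterval(npmr, bounds) + 1L
  structure(list(id1 = pmr$id1, id2 = pmr$id2, normalized_pmr = npmr,
                 degree = labels[idx],
                 expected = stats::setNames(c(0.5, 0.75, 0.875, 0.9375, 1) * b,
                                            labels),
                 low_confidence = pmr$n_overlap < min_overlap),
            class = "degree_call")
}

#' Degree calls for all pairs
#'
#' Convenience wrapper: PMR for all pairs, then [classify_degree()] against
#' a baseline.
#'
#' @inheritParams pmr_all_pairs
#' @inheritParams classify_degree
#' @return data frame: pair ids, overlap, pmr, se, normalized_pmr, degree,
#'   low_confidence.
#' @export
classify_all_pairs <- function(genotypes, baseline,
                               ids = genotypes$individual_ids, panel = NULL,
                               autosomes_only = TRUE, min_overlap = 10000) {
  tab <- pmr_all_pairs(genotypes, ids, panel, autosomes_only)
  b <- if (inherits(baseline, "pmr_baseline")) baseline$b else baseline
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    classify_degree(list(id1 = tab$id1[i], id2 = tab$id2[i], pmr = tab$pmr[i],
                         n_overlap = tab$n_overlap[i]), b, min_overlap)
  })
  tab$normalized_pmr <- vapply(calls, `[[`, numeric(1), "normalized_pmr")
  tab$degree <- vapply(calls, `[[`, character(1), "degree")
  tab$low_confidence <- vapply(calls, `[[`, logical(1), "low_confidence")
  tab
}

#' Genotype likelihoods from read counts
#'
#' For each site, the likelihood of diploid genotype `g` (alt dosage 0/1/2)
#' is the binomial probability of the observed alt reads with alt-read
#' probability `e`, `1/2`, `1 - e` respectively, where `e` is the per-read
#' error rate. Likelihoods are normalized to sum to one per site;
#' zero-depth sites are uninformative, `(1/3, 1/3, 1/3)`.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @param base_error per-read flip probability, in `(0, 0.5)`.
#' @return numeric matrix `n_sites x 3` with columns `g0`, `g1`, `g2`.
#' @export
genotype_likelihoods <- function(ref_count, alt_count, base_error = 0.01) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("genotype_likelihoods: counts must be >= 0", call. = FALSE)
  }
  if (base_error <= 0 || base_error >= 0.5) {
    stop("genotype_likelihoods: base_error must be in (0, 0.5)", call. = FALSE)
  }
  n <- ref_count + alt_count
  gl <- cbind(g0 = stats::dbinom(alt_count, n, base_error),
              g1 = stats::dbinom(alt_count, n, 0.5),
              g2 = stats::dbinom(alt_count, n, 1 - base_error))
  gl[n == 0, ] <- 1
  gl / rowSums(gl)
}

# joint genotype probability arrays P(gi, gj | IBD = m, p) for the three IBD
# states, vectorized over sites. Returns list of three S x 9 matrices in
# column-major (gi, gj) order: (0,0),(1,0),(2,0),(0,1),...
ibd_joint_probs <- function(p) {
  q <- 1 - p
  hwe <- cbind(q^2, 2 * p * q, p^2)
  # m = 0: independent HWE
  P0 <- cbind(hwe[, 1] * hwe[, 1], hwe[, 2] * hwe[, 1], hwe[, 3] * hwe[, 1],
              hwe[, 1] * hwe[, 2], hwe[, 2] * hwe[, 2], hwe[, 3] * hwe[, 2],
              hwe[, 1] * hwe[, 3], hwe[, 2] * hwe[, 3], hwe[, 3] * hwe[, 3])
  # m = 1: one allele shared IBD, the other drawn from the population:
  # gi = s + xi, gj = s + xj with s, xi, xj ~ Bernoulli(p) independent
  P1 <- cbind(q^3,        p * q^2,   0,
              p * q^2,    p * q,     p^2 * q,
              0,          p^2 * q,   p^3)
  # m = 2: both alleles shared; diagonal HWE
  zero <- numeric(length(p))
  P2 <- cbind(hwe[, 1], zero, zero, zero, hwe[, 2], zero, zero, zero, hwe[, 3])
  list(P0 = P0, P1 = P1, P2 = P2)
}

#' Maximum-likelihood IBD coefficients (k0, k1, k2) for a pair
#'
#' Estimates the probabilities that the pair shares 0, 1 or 2 alleles
#' identical by descent at a locus by maximizing the genotype-likelihood
#' mixture `prod_s sum_m k_m P(data_s | IBD = m, p_s)` over the simplex
#' with an EM algorithm (the lcMLkin model). The shared-allele state treats
#' both individuals symmetrically (one population allele is shared, each
#' individual's remaining allele is an independent population draw), which
#' equals the average of the two directional conventions. The EM iteration
#' is SQUAREM-accelerated (plain EM creeps when the optimum lies on the
#' simplex boundary, as for parent-offspring pairs); every accelerated step
#' is accepted only if it does not decrease the likelihood, so the
#' log-likelihood trace is non-decreasing. Convergence when the
#' log-likelihood gain per cycle drops below `tol`; non-convergence within
#' `max_iter` EM steps is flagged and the last iterate returned.
#'
#' @param gl1,gl2 `n_sites x 3` genotype-likelihood matrices from
#'   [genotype_likelihoods()].
#' @param freqs per-site population alt-allele frequencies in (0, 1).
#' @param tol,max_iter EM convergence controls.
#' @param min_sites minimum number of doubly informative sites.
#' @return list of class `ibd_coefficients`: `k0`, `k1`, `k2`, `kappa`,
#'   `log_likelihood`, `n_sites_used`, `n_iter`, `converged`.
#' @export
estimate_ibd_coefficients <- function(gl1, gl2, freqs, tol = 1e-6,
                                      max_iter = 1000, min_sites = 100) {
  # sites informative in both individuals (non-uniform GL) and with proper p
  informative <- function(gl) abs(gl[, 1] - gl[, 2]) > 1e-12 |
    abs(gl[, 2] - gl[, 3]) > 1e-12
  use <- informative(gl1) & informative(gl2) & freqs > 0 & freqs < 1
  n_use <- sum(use)
  if (n_use < min_sites) {
    stop(sprintf("estimate_ibd_coefficients: only %d informative sites (need >= %d)",
                 n_use, min_sites), call. = FALSE)
  }
  g1 <- gl1[use, , drop = FALSE]
  g2 <- gl2[use, , drop = FALSE]
  J <- ibd_joint_probs(freqs[use])
  # P_m(s) = sum_{gi,gj} GL1(gi) GL2(gj) J_m[gi,gj]
  w <- cbind(g1[, 1] * g2[, 1], g1[, 2] * g2[, 1], g1[, 3] * g2[, 1],
             g1[, 1] * g2[, 2], g1[, 2] * g2[, 2], g1[, 3] * g2[, 2],
             g1[, 1] * g2[, 3], g1[, 2] * g2[, 3], g1[, 3] * g2[, 3])
  P <- cbind(rowSums(w * J$P0), rowSums(w * J$P1), rowSums(w * J$P2))
  em_step <- function(k) {
    mix <- as.vector(P %*% k)
    k_new <- colMeans(P * rep(k, each = nrow(P)) / mix)
    k_new / sum(k_new)
  }
  loglik <- function(k) sum(log(as.vector(P %*% k)))
  project <- function(k) {
    k <- pmax(k, 0)
    s <- sum(k)
    if (s <= 0) rep(1 / 3, 3) else k / s
  }
  # EM with SQUAREM-style acceleration: plain EM creeps near the simplex
  # boundary (parent-offspring pairs), so each cycle extrapolates two EM
  # steps and falls back to the unaccelerated iterate whenever the
  # extrapolation would lower the likelihood -- monotonicity is preserved
  k <- c(1, 1, 1) / 3
  ll_old <- loglik(k)
  ll_trace <- ll_old
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    k1 <- em_step(k)
    k2 <- em_step(k1)
    it <- it + 2L
    r <- k1 - k
    v <- (k2 - k1) - r
    if (sum(v^2) > 1e-30) {
      a <- min(-1, -sqrt(sum(r^2) / sum(v^2)))
      kp <- em_step(project(k - 2 * a * r + a^2 * v))
      it <- it + 1L
      if (loglik(kp) >= loglik(k2)) k2 <- kp
    }
    k <- k2
    ll <- loglik(k)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && ll - ll_old < tol) {
      ll_old <- ll
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("estimate_ibd_coefficients: EM did not converge; last iterate returned",
            call. = FALSE)
  }
  structure(list(k0 = k[1], k1 = k[2], k2 = k[3],
                 kappa = k[2] / 4 + k[3] / 2,
                 log_likelihood = ll_old, n_sites_used = n_use,
                 n_iter = it, converged = converged, ll_trace = ll_trace),
            class = "ibd_coefficients")
}

#' Distinguish parent-offspring from full siblings
#'
#' First-degree pairs share the same kinship coefficient but differ in IBD
#' state: parent-offspring pairs share exactly one allele everywhere
#' (k = (0, 1, 0)) while full siblings share two alleles at a quarter of
#' sites (k = (1/4, 1/2, 1/4)). Rule: `parent_offspring` if `k0 < 0.05` and
#' `k2 < 0.1`; `full_sibling` if `k0 >= 0.1` and `k2 >= 0.1`; otherwise
#' `undetermined`. Age classes are attached as advisory context only and
#' never override the genetic call.
#'
#' @param ibd an `ibd_coefficients` result (or list with `k0`, `k1`, `k2`).
#' @param age_classes optional length-2 character vector of age classes.
#' @return list with `type` and `age_note`.
#' @export
disambiguate_first_degree <- function(ibd, age_classes = NULL) {
  type <- if (ibd$k0 < 0.05 && ibd$k2 < 0.1) "parent_offspring"
  else if (ibd$k0 >= 0.1 && ibd$k2 >= 0.1) "full_sibling"
  else "undetermined"
  note <- if (!is.null(age_classes)) {
    paste("age classes:", paste(age_classes, collapse = "/"))
  } else NA_character_
  list(type = type, age_note = note)
}

#' Prune relatives for group-based analyses
#'
#' Returns a maximum-size subset of individuals containing no pair related
#' at second degree or closer (an exact maximum independent set of the
#' relatedness graph; groups here are small). Among equally large sets, the
#' one with higher total site coverage is preferred, then the
#' lexicographically smallest id vector.
#'
#' @param degree_calls data frame `id1`, `id2`, `degree` for all pairs.
#' @param ids individuals to consider (default: all ids in `degree_calls`).
#' @param coverage optional named numeric vector of per-individual site
#'   counts used for tie-breaking.
#' @return character vector of retained ids (sorted).
#' @export
prune_relatives <- function(degree_calls, ids = NULL, coverage = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(degree_calls$id1, degree_calls$id2)))
  n <- length(ids)
  if (n == 0) return(character(0))
  if (n > 16) stop("prune_relatives: exact search supports up to 16 individuals",
                   call. = FALSE)
  close_deg <- c("identical", "first", "second")
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(degree_calls))) {
    if (degree_calls$degree[r] %in% close_deg) {
      i <- match(degree_calls$id1[r], ids)
      j <- match(degree_calls$id2[r], ids)
      if (!is.na(i) && !is.na(j)) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  cov <- if (is.null(coverage)) stats::setNames(numeric(n), ids) else
    coverage[ids]
  cov[is.na(cov)] <- 0
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < length(best %||% integer(0))) next
    if (any(adj[members, members])) next
    key <- list(size = length(members), cov = sum(cov[members]),
                ids = paste(ids[members], collapse = ","))
    better <- is.null(best) || key$size > best_key$size ||
      (key$size == best_key$size && key$cov > best_key$cov) ||
      (key$size == best_key$size && key$cov == best_key$cov &&
         key$ids < best_key$ids)
    if (better) { best <- members; best_key <- key }
  }
  sort(ids[best])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
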