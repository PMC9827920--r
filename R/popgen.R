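#' Per-population allele frequencies
#'
#' Computes per-SNP sample alt-allele frequencies and observed allele counts
#' for each population. Haploid calls contribute one allele, diploid calls
#' two; missing calls are excluded. A site with zero observed alleles is
#' missing (`NA` frequency, count 0).
#'
#' @param genotypes a [genotype_matrix()] (haploid or diploid).
#' @param populations character label per individual (in matrix row order),
#'   or a data frame `id`, `population`.
#' @return list of class `group_freqs` with `freq` and `count` matrices
#'   (`n_snps x n_pops`) and `populations`.
#' @export
group_frequencies <- function(genotypes, populations) {
  if (is.data.frame(populations)) {
    labels <- populations$population[match(genotypes$individual_ids,
                                           populations$id)]
    if (any(is.na(labels))) {
      stop("group_frequencies: individual without a population label",
           call. = FALSE)
    }
  } else {
    if (length(populations) != length(genotypes$individual_ids)) {
      stop("group_frequencies: one label per individual required", call. = FALSE)
    }
    labels <- as.character(populations)
  }
  ploidy_n <- if (genotypes$ploidy == "haploid") 1L else 2L
  pops <- unique(labels)
  g <- genotypes$calls
  freq <- count <- matrix(NA_real_, nrow = ncol(g), ncol = length(pops),
                          dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    rows <- which(labels == pops[j])
    sub <- g[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub)) * ploidy_n
    alt <- colSums(sub, na.rm = TRUE)
    count[, j] <- n_called
    freq[, j] <- ifelse(n_called > 0, alt / n_called, NA_real_)
  }
  structure(list(freq = freq, count = count, populations = pops),
            class = "group_freqs")
}

#' Pool allele counts across two group-frequency sets
#'
#' Combines per-population allele counts from two [group_frequencies()]
#' results over the same SNPs (e.g. a haploid ancient set and a diploid
#' modern set assigned to the same population labels). Frequencies are
#' re-derived from the pooled counts.
#'
#' @param gf1,gf2 `group_freqs` objects over the same SNP panel.
#' @return a `group_freqs` over the union of the population labels.
#' @export
pool_group_frequencies <- function(gf1, gf2) {
  if (nrow(gf1$freq) != nrow(gf2$freq)) {
    stop("pool_group_frequencies: SNP counts differ", call. = FALSE)
  }
  pops <- union(gf1$populations, gf2$populations)
  n <- nrow(gf1$freq)
  freq <- count <- matrix(NA_real_, n, length(pops),
                          dimnames = list(NULL, pops))
  for (p in pops) {
    alt <- tot <- numeric(n)
    for (gf in list(gf1, gf2)) {
      if (p %in% gf$populations) {
        c_p <- gf$count[, p]
        f_p <- gf$freq[, p]
        alt <- alt + ifelse(c_p > 0, f_p * c_p, 0)
        tot <- tot + c_p
      }
    }
    count[, p] <- tot
    freq[, p] <- ifelse(tot > 0, alt / tot, NA_real_)
  }
  structure(list(freq = freq, count = count, populations = pops),
            class = "group_freqs")
}

# accept group_freqs or a plain frequency matrix
as_freq_matrix <- function(x) {
  if (inherits(x, "group_freqs")) x$freq else as.matrix(x)
}

#' Contiguous jackknife blocks from a SNP panel
#'
#' Assigns each SNP to a contiguous window per chromosome: `window_cm` cM
#' wide from genetic positions when present, falling back to `window_mb`
#' Mb physical windows (with a message) when any genetic position is
#' missing.
#'
#' @param panel a [snp_panel()].
#' @param window_cm genetic window width in cM.
#' @param window_mb physical fallback window in Mb.
#' @return integer block index per SNP.
#' @export
assign_jackknife_blocks <- function(panel, window_cm = 5, window_mb = 5) {
  if (window_cm <= 0 || window_mb <= 0) {
    stop("assign_jackknife_blocks: window must be > 0", call. = FALSE)
  }
  use_genetic <- !anyNA(panel$genetic_position)
  if (!use_genetic) {
    message("assign_jackknife_blocks: genetic positions absent, using ",
            window_mb, " Mb physical windows")
  }
  pos <- if (use_genetic) panel$genetic_position else
    panel$physical_position / 1e6
  width <- if (use_genetic) window_cm else window_mb
  block <- integer(nrow(panel))
  offset <- 0L
  for (chr in unique(panel$chromosome)) {
    sel <- panel$chromosome == chr
    idx <- floor((pos[sel] - min(pos[sel])) / width)
    block[sel] <- offset + as.integer(factor(idx))
    offset <- max(block[sel])
  }
  block
}

#' Weighted delete-one-block jackknife
#'
#' Estimate and standard error of a ratio statistic `sum(num)/sum(den)`
#' over SNPs, with blocks deleted one at a time and weighted by their SNP
#' counts (Busing-style weighted jackknife). For equal block sizes this
#' reduces to the classic delete-one jackknife.
#'
#' @param num per-SNP numerator terms (statistic contributions).
#' @param den per-SNP denominator terms (default 1 per usable SNP, giving a
#'   mean).
#' @param block integer block assignment per SNP.
#' @return list with `estimate`, `se`, `n_blocks`, `n_snps`.
#' @export
block_jackknife <- function(num, block, den = rep(1, length(num))) {
  keep <- !is.na(num)
  num <- num[keep]; den <- den[keep]; block <- block[keep]
  blocks <- sort(unique(block))
  g <- length(blocks)
  if (g < 2) {
    stop("block_jackknife: need >= 2 non-empty blocks (reduce window or add data)",
         call. = FALSE)
  }
  S <- sum(num); D <- sum(den); n <- length(num)
  s_b <- vapply(blocks, function(b) sum(num[block == b]), numeric(1))
  d_b <- vapply(blocks, function(b) sum(den[block == b]), numeric(1))
  m_b <- vapply(blocks, function(b) sum(block == b), numeric(1))
  theta <- S / D
  theta_b <- (S - s_b) / (D - d_b)        # leave-one-block-out estimates
  h <- n / m_b
  theta_J <- g * theta - sum((1 - m_b / n) * theta_b)
  tau <- h * theta - (h - 1) * theta_b
  var_J <- mean((tau - theta_J)^2 / (h - 1))
  list(estimate = theta, se = sqrt(var_J), n_blocks = g, n_snps = n)
}

# weighted jackknife covariance for a vector statistic. `full` is the
# length-k full-data estimate, `leave_out` a g x k matrix of delete-one
# estimates, m_b the per-block SNP counts.
jackknife_covariance <- function(full, leave_out, m_b) {
  n <- sum(m_b)
  g <- length(m_b)
  h <- n / m_b
  theta_J <- g * full - colSums((1 - m_b / n) * leave_out)
  tau <- outer(h, full) - (h - 1) * leave_out
  centred <- sweep(tau, 2, theta_J) / sqrt(h - 1)
  crossprod(centred) / g
}

# internal f-statistic engine: per-SNP terms + usability mask
fstat_terms <- function(freq, cols, type = c("f3", "f4")) {
  type <- match.arg(type)
  f <- freq[, cols, drop = FALSE]
  usable <- rowSums(is.na(f)) == 0
  term <- rep(NA_real_, nrow(f))
  if (type == "f3") {
    term[usable] <- (f[usable, 1] - f[usable, 2]) * (f[usable, 1] - f[usable, 3])
  } else {
    term[usable] <- (f[usable, 1] - f[usable, 2]) * (f[usable, 3] - f[usable, 4])
  }
  term
}

fstat_result <- function(name, args, term, block) {
  jk <- block_jackknife(term, block)
  structure(list(statistic = name, args = args, estimate = jk$estimate,
                 se = jk$se, z = jk$estimate / jk$se, n_blocks = jk$n_blocks,
                 n_snps = jk$n_snps),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6f  se %.6f  Z %.2f  (%d SNPs, %d blocks)\n",
              x$statistic, paste(x$args, collapse = ", "), x$estimate, x$se,
              x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' Outgroup-f3 statistic
#'
#' `f3(O; A, B)`: the mean over usable SNPs of `(o - a)(o - b)`, measuring
#' the shared drift of A and B relative to outgroup O; higher means closer
#' affinity. A SNP is usable iff all three populations have data. Standard
#' error by weighted block jackknife. No small-sample heterozygosity
#' correction is applied (the intended use is affinity ranking of
#' pseudo-haploid data).
#'
#' @param freqs a `group_freqs` or frequency matrix with named columns.
#' @param outgroup,popA,popB column names.
#' @param block block assignment from [assign_jackknife_blocks()].
#' @return an `fstat_result`.
#' @export
f3_outgroup <- function(freqs, outgroup, popA, popB, block) {
  f <- as_freq_matrix(freqs)
  term <- fstat_terms(f, c(outgroup, popA, popB), "f3")
  fstat_result("f3", c(outgroup, popA, popB), term, block)
}

#' f4 statistic
#'
#' `f4(A, B; C, D)`: mean over usable SNPs of `(a - b)(c - d)`; zero under
#' cladality of (A,B) vs (C,D). SNP usable iff all four populations have
#' data; jackknife estimate/se/Z as in [f3_outgroup()].
#'
#' @inheritParams f3_outgroup
#' @param popA,popB,popC,popD column names.
#' @return an `fstat_result`.
#' @export
f4 <- function(freqs, popA, popB, popC, popD, block) {
  f <- as_freq_matrix(freqs)
  term <- fstat_terms(f, c(popA, popB, popC, popD), "f4")
  fstat_result("f4", c(popA, popB, popC, popD), term, block)
}

# f4 matrix machinery shared by qpWave/qpAdm: left l0, li vs right r0, rj.
# Returns full-data vector, leave-out matrix, per-block counts, and the
# usable-SNP count. Usability = intersection over ALL left+right pops.
f4_matrix_jackknife <- function(freq, left, right, block) {
  cols <- c(left, right)
  usable <- rowSums(is.na(freq[, cols, drop = FALSE])) == 0
  if (!any(usable)) stop("no SNPs usable for all populations", call. = FALSE)
  f <- freq[usable, , drop = FALSE]
  blk <- block[usable]
  a <- length(left); b <- length(right)
  k <- (a - 1) * (b - 1)
  terms <- matrix(NA_real_, nrow = nrow(f), ncol = k)
  idx <- 0L
  for (j in seq_len(b - 1)) {
    for (i in seq_len(a - 1)) {
      idx <- idx + 1L
      terms[, idx] <- (f[, left[1]] - f[, left[i + 1]]) *
        (f[, right[1]] - f[, right[j + 1]])
    }
  }
  blocks <- sort(unique(blk))
  g <- length(blocks)
  if (g < 2) stop("need >= 2 jackknife blocks", call. = FALSE)
  tot <- colSums(terms)
  n <- nrow(terms)
  sums_b <- rowsum(terms, blk)            # g x k block sums
  m_b <- as.vector(rowsum(rep(1, n), blk))
  full <- tot / n
  leave_out <- sweep(-sums_b, 2, tot, "+") / (n - m_b)
  list(full = full, leave_out = leave_out, m_b = m_b, n_snps = n,
       n_blocks = g, a = a, b = b)
}

# rank-r GLS fit of a matrix F (vectorized as f) under covariance C.
# Returns the chi-square statistic. r = 0 tests F == 0.
rank_fit_stat <- function(f, C, a1, b1, r, ridge_tol = 1e12) {
  Ci <- solve_regularized(C, ridge_tol)
  if (r == 0) return(drop(t(f) %*% Ci %*% f))
  Fm <- matrix(f, nrow = a1, ncol = b1)
  sv <- svd(Fm)
  A <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r, r)
  B <- t(sv$v[, seq_len(r), drop = FALSE])
  obj_old <- Inf
  for (it in 1:100) {
    # solve for A given B: vec(AB) = (t(B) %x% I) vec(A)
    M <- t(B) %x% diag(a1)
    A <- matrix(solve(t(M) %*% Ci %*% M, t(M) %*% Ci %*% f), nrow = a1)
    # solve for B given A: vec(AB) = (I %x% A) vec(B)
    M <- diag(b1) %x% A
    B <- matrix(solve(t(M) %*% Ci %*% M, t(M) %*% Ci %*% f), nrow = r)
    e <- f - as.vector(A %*% B)
    obj <- drop(t(e) %*% Ci %*% e)
    if (obj_old - obj < 1e-12) break
    obj_old <- obj
  }
  obj
}

solve_regularized <- function(C, ridge_tol = 1e12) {
  kap <- tryCatch(suppressWarnings(kappa(C, exact = TRUE)),
                  error = function(e) Inf)
  inv <- if (is.finite(kap) && kap > 0 && kap <= ridge_tol) {
    tryCatch(solve(C), error = function(e) NULL)
  } else NULL
  if (is.null(inv)) {
    warning(sprintf("near-singular covariance (condition number %.3g); ridge added",
                    kap), call. = FALSE)
    lambda <- 1e-9 * mean(diag(C))
    if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-24
    inv <- solve(C + diag(lambda, nrow(C)))
  }
  inv
}

#' qpWave-style rank test
#'
#' Tests whether the matrix of `f4(l0, li; r0, rj)` statistics between a set
#' of `left` and `right` populations is consistent with rank `r`, i.e.
#' whether the left populations trace back to at most `r + 1` independent
#' ancestry streams relative to the rights. The covariance of the f4 matrix
#' is estimated by weighted block jackknife; the minimized quadratic form
#' for a rank-`r` approximation is compared to a chi-square with
#' `(|left|-1-r)(|right|-1-r)` degrees of freedom. SNPs must be present in
#' all left and right populations.
#'
#' @param freqs a `group_freqs` or frequency matrix.
#' @param left,right population (column) names; `|left| >= 2`,
#'   `|right| >= |left|`.
#' @param block per-SNP block assignment.
#' @param rank tested rank `r`, `0 <= r <= |left| - 1`.
#' @return list of class `qpwave_result`: `statistic`, `df`, `p_value`,
#'   `rank`, `n_snps`, `n_blocks`.
#' @export
qpwave_rank_test <- function(freqs, left, right, block, rank = 0) {
  if (length(left) < 2) stop("qpwave: need >= 2 left populations", call. = FALSE)
  if (length(right) < length(left)) {
    stop("qpwave: need |right| >= |left|", call. = FALSE)
  }
  f <- as_freq_matrix(freqs)
  jk <- f4_matrix_jackknife(f, left, right, block)
  a1 <- jk$a - 1L; b1 <- jk$b - 1L
  df <- (a1 - rank) * (b1 - rank)
  if (df <= 0) {
    return(structure(list(statistic = 0, df = 0L, p_value = 1, rank = rank,
                          n_snps = jk$n_snps, n_blocks = jk$n_blocks),
                     class = "qpwave_result"))
  }
  C <- jackknife_covariance(jk$full, jk$leave_out, jk$m_b)
  stat <- rank_fit_stat(jk$full, C, a1, b1, rank)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 rank = rank, n_snps = jk$n_snps, n_blocks = jk$n_blocks),
            class = "qpwave_result")
}

#' qpAdm-style admixture weights
#'
#' Models the target's allele frequencies as a mixture of the source
#' populations, using the right populations as references: the weights
#' solve the generalized-least-squares condition
#' `f4(target - sum_i w_i source_i, base; r0, rj) = 0` for all right pairs,
#' subject to `sum_i w_i = 1` (the base population's contribution cancels
#' under the constraint; the first right population is used). Standard
#' errors come from a delete-one-block jackknife of the whole fit; the
#' model's rank-test tail probability is the qpWave test of rank
#' `|sources| - 1` on the left set `(target, sources)`. Weights may be
#' negative, in which case `feasible` is `FALSE`.
#'
#' @param freqs a `group_freqs` or frequency matrix.
#' @param target target population name.
#' @param sources character vector of source population names (>= 1).
#' @param rights character vector of right populations, disjoint from
#'   target/sources; `|rights| >= |sources| + 1`.
#' @param block per-SNP block assignment.
#' @return list of class `qpadm_result`: `weights`, `se`, `p_value`,
#'   `feasible`, `n_snps`, `n_blocks`, `condition_number`.
#' @export
qpadm_weights <- function(freqs, target, sources, rights, block) {
  if (length(sources) < 1) stop("qpadm: need >= 1 source", call. = FALSE)
  if (any(c(target, sources) %in% rights)) {
    stop("qpadm: rights must be disjoint from target and sources", call. = FALSE)
  }
  if (length(rights) < length(sources) + 1) {
    stop("qpadm: need |rights| >= |sources| + 1", call. = FALSE)
  }
  f <- as_freq_matrix(freqs)
  cols <- c(target, sources, rights)
  usable <- rowSums(is.na(f[, cols, drop = FALSE])) == 0
  if (!any(usable)) stop("qpadm: no usable SNPs", call. = FALSE)
  f <- f[usable, , drop = FALSE]
  blk <- block[usable]
  s <- length(sources)
  base <- rights[1]
  nr <- length(rights) - 1L
  # per-SNP terms for y_j and X_ij
  n <- nrow(f)
  terms_y <- matrix(NA_real_, n, nr)
  terms_X <- array(NA_real_, c(n, s, nr))
  for (j in seq_len(nr)) {
    d <- f[, base] - f[, rights[j + 1]]
    terms_y[, j] <- (f[, target] - f[, base]) * d
    for (i in seq_len(s)) {
      terms_X[, i, j] <- (f[, sources[i]] - f[, base]) * d
    }
  }
  blocks <- sort(unique(blk))
  g <- length(blocks)
  if (g < 2) stop("qpadm: need >= 2 jackknife blocks", call. = FALSE)
  m_b <- as.vector(rowsum(rep(1, n), blk))
  y_sum <- colSums(terms_y)
  y_bsum <- rowsum(terms_y, blk)
  X_sum <- apply(terms_X, c(2, 3), sum)
  X_bsum <- apply(terms_X, c(2, 3), function(v) rowsum(v, blk))  # g x s x nr
  y_full <- y_sum / n
  X_full <- X_sum / n

  fit_w <- function(y, X, Ci) {
    # KKT system for min (y - X'w)' Ci (y - X'w) s.t. sum(w) = 1;
    # the solution is invariant to the scale of Ci, so normalize it to
    # keep the bordered system well conditioned
    Ci <- Ci / mean(diag(Ci))
    XtC <- X %*% Ci              # s x nr
    A <- rbind(cbind(XtC %*% t(X), rep(1, s)), c(rep(1, s), 0))
    rhs <- c(XtC %*% y, 1)
    drop(solve(A, rhs))[seq_len(s)]
  }

  # iterate covariance: start with identity, then jackknife cov of residual
  Ci <- diag(nr)
  w <- fit_w(y_full, X_full, Ci)
  cond <- NA_real_
  for (rep_it in 1:2) {
    res_full <- y_full - drop(t(X_full) %*% w)
    res_lo <- matrix(NA_real_, g, nr)
    for (bi in seq_len(g)) {
      y_lo <- (y_sum - y_bsum[bi, ]) / (n - m_b[bi])
      X_lo <- (X_sum - X_bsum[bi, , ]) / (n - m_b[bi])
      X_lo <- matrix(X_lo, nrow = s)
      res_lo[bi, ] <- y_lo - drop(t(X_lo) %*% w)
    }
    C <- jackknife_covariance(res_full, res_lo, m_b)
    cond <- tryCatch(suppressWarnings(kappa(C, exact = TRUE)),
                     error = function(e) Inf)
    Ci <- solve_regularized(C)
    w <- fit_w(y_full, X_full, Ci)
  }
  # delete-one-block refits for weight standard errors
  w_lo <- matrix(NA_real_, g, s)
  for (bi in seq_len(g)) {
    y_lo <- (y_sum - y_bsum[bi, ]) / (n - m_b[bi])
    X_lo <- matrix((X_sum - X_bsum[bi, , ]) / (n - m_b[bi]), nrow = s)
    w_lo[bi, ] <- fit_w(y_lo, X_lo, Ci)
  }
  Cw <- jackknife_covariance(w, w_lo, m_b)
  se <- sqrt(diag(Cw))
  p <- if (s >= 2) {
    qpwave_rank_test(f, c(target, sources), rights, blk, rank = s - 1)$p_value
  } else {
    qpwave_rank_test(f, c(target, sources), rights, blk, rank = 0)$p_value
  }
  structure(list(target = target, sources = sources, rights = rights,
                 weights = stats::setNames(w, sources),
                 se = stats::setNames(se, sources), p_value = p,
                 feasible = all(w >= 0 & w <= 1), n_snps = n, n_blocks = g,
                 condition_number = cond),
            class = "qpadm_result")
}

#' @export
print.qpadm_result <- function(x, ...) {
  cat(sprintf("qpAdm: %s ~ %s  (p = %.4g, %d SNPs)\n", x$target,
              paste(x$sources, collapse = " + "), x$p_value, x$n_snps))
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %-12s %7.4f +/- %.4f\n", names(x$weights)[i],
                x$weights[i], x$se[i]))
  }
  if (!x$feasible) cat("  (infeasible: weight outside [0, 1])\n")
  invisible(x)
}
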