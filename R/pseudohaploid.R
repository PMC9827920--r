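#' Pseudo-haploid genotype calling
#'
#' Represents each individual at each site by a single randomly sampled
#' allele, the standard genotype representation for low-coverage ancient
#' genomes. The source is either per-site read counts (sample one read
#' uniformly; its allele is the call) or a diploid genotype matrix (sample
#' one of the two alleles uniformly). Sites with zero reads, or missing
#' diploid genotypes, are missing in the output. Deterministic given `seed`.
#'
#' @param x a diploid [genotype_matrix()], or a `read_counts` object from
#'   [simulate_reads()] (a list with integer matrices `ref` and `alt`).
#' @param seed integer seed (required).
#' @return haploid [genotype_matrix()].
#' @export
pseudo_haploidize <- function(x, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("pseudo_haploidize: a seed is required", call. = FALSE)
  }
  with_seed(seed, {
    if (inherits(x, "genotype_matrix")) {
      if (x$ploidy != "diploid") {
        stop("pseudo_haploidize: genotype input must be diploid", call. = FALSE)
      }
      g <- x$calls
      # P(alt call) = dosage / 2; hets are a fair coin, homs forced
      u <- matrix(stats::runif(length(g)), nrow = nrow(g))
      hap <- ifelse(u < g / 2, 1L, 0L)
      hap[is.na(g)] <- NA_integer_
      genotype_matrix(hap, "haploid", x$individual_ids)
    } else if (is.list(x) && all(c("ref", "alt") %in% names(x))) {
      ref <- x$ref; alt <- x$alt
      if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
        stop("pseudo_haploidize: negative read counts", call. = FALSE)
      }
      tot <- ref + alt
      # a uniformly sampled read is alt with probability alt/total
      u <- matrix(stats::runif(length(tot)), nrow = nrow(tot))
      hap <- ifelse(u < alt / pmax(tot, 1L), 1L, 0L)
      hap[tot == 0L] <- NA_integer_
      genotype_matrix(hap, "haploid",
                      if (!is.null(rownames(ref))) rownames(ref) else NULL)
    } else {
      stop("pseudo_haploidize: input must be a diploid genotype_matrix or read counts",
           call. = FALSE)
    }
  })
}

#' Coverage summary container
#'
#' Per-individual mean sequencing depth at panel sites on autosomes and the
#' X and Y chromosomes, used for coverage-based genetic sexing.
#'
#' @param id individual ids.
#' @param autosome,x,y non-negative mean depths.
#' @return data frame of class `coverage_summary`.
#' @export
coverage_summary <- function(id, autosome, x, y) {
  d <- data.frame(id = as.character(id), autosome = as.numeric(autosome),
                  x = as.numeric(x), y = as.numeric(y),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(d[-1]))) || any(as.matrix(d[-1]) < 0)) {
    stop("coverage_summary: depths must be finite and non-negative", call. = FALSE)
  }
  class(d) <- c("coverage_summary", "data.frame")
  d
}

#' Assign genetic sex from relative sex-chromosome coverage
#'
#' Compares X and Y coverage with autosomal coverage. With ratios
#' `rx = X/autosome` and `ry = Y/autosome`: XX iff `rx >= x_female_min` and
#' `ry <= y_female_max`; XY iff `rx <= x_male_max` and `ry >= y_male_min`;
#' otherwise unassigned. Individuals with zero autosomal depth are
#' unassigned with a warning. The defaults are conventional screening
#' thresholds and are invariant to uniform scaling of all depths.
#'
#' @param coverage a [coverage_summary()].
#' @param x_female_min,x_male_max,y_male_min,y_female_max ratio thresholds.
#' @return data frame with columns `id`, `x_ratio`, `y_ratio`, `genetic_sex`.
#' @export
assign_genetic_sex <- function(coverage, x_female_min = 0.8, x_male_max = 0.6,
                               y_male_min = 0.3, y_female_max = 0.1) {
  zero <- coverage$autosome <= 0
  if (any(zero)) {
    warning(sprintf("zero autosomal depth, unassigned: %s",
                    paste(coverage$id[zero], collapse = ", ")), call. = FALSE)
  }
  rx <- ifelse(zero, NA_real_, coverage$x / coverage$autosome)
  ry <- ifelse(zero, NA_real_, coverage$y / coverage$autosome)
  sex <- rep("unassigned", nrow(coverage))
  sex[!zero & rx >= x_female_min & ry <= y_female_max] <- "XX"
  sex[!zero & rx <= x_male_max & ry >= y_male_min] <- "XY"
  data.frame(id = coverage$id, x_ratio = rx, y_ratio = ry, genetic_sex = sex,
             stringsAsFactors = FALSE)
}
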