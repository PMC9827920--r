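#' SNP panel metadata
#'
#' A `snp_panel` describes the sites of a capture panel: one row per SNP with
#' identifier, chromosome label, physical position (1-based bp), genetic
#' position (cM, may be `NA`) and the two alleles. Positions must be
#' non-decreasing within a chromosome, alleles distinct, ids unique.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome character (or coercible) chromosome labels; autosomes are
#'   the labels `"1"`..`"22"`.
#' @param physical_position integer bp positions, 1-based.
#' @param genetic_position numeric cM positions or `NA`.
#' @param ref_allele,alt_allele single-character alleles, distinct per SNP.
#' @return A data frame of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chromosome, physical_position,
                      genetic_position = NA_real_, ref_allele = "A",
                      alt_allele = "G") {
  n <- length(snp_id)
  panel <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    physical_position = as.integer(physical_position),
    genetic_position = rep_len(as.numeric(genetic_position), n),
    ref_allele = rep_len(as.character(ref_allele), n),
    alt_allele = rep_len(as.character(alt_allele), n),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  validate_snp_panel(panel)
  panel
}

validate_snp_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id)) {
    stop("snp_panel: snp_ids must be unique", call. = FALSE)
  }
  if (any(panel$ref_allele == panel$alt_allele)) {
    stop("snp_panel: ref and alt alleles must differ", call. = FALSE)
  }
  for (chr in unique(panel$chromosome)) {
    pos <- panel$physical_position[panel$chromosome == chr]
    if (is.unsorted(pos)) {
      stop(sprintf("snp_panel: positions not non-decreasing on chromosome %s",
                   chr), call. = FALSE)
    }
  }
  invisible(panel)
}

#' Is a chromosome label an autosome?
#'
#' Autosomes are the labels "1" through "22" (kept verbatim as strings).
#' @param chromosome character vector of chromosome labels.
#' @return logical vector.
#' @export
is_autosome <- function(chromosome) chromosome %in% as.character(1:22)

#' Genotype matrix container
#'
#' Holds calls for `individuals x SNPs`, either haploid (0 = ref allele,
#' 1 = alt allele) or diploid (alt-allele dosage 0/1/2), with `NA` as the
#' missing value. Column count must equal the panel length.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns; `NA`
#'   for missing.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @param individual_ids character vector, one per row.
#' @param panel optional `snp_panel` to check column count against.
#' @return Object of class `genotype_matrix`: a list with elements `calls`,
#'   `ploidy`, `individual_ids`.
#' @export
genotype_matrix <- function(calls, ploidy = c("diploid", "haploid"),
                            individual_ids = rownames(calls), panel = NULL) {
  ploidy <- match.arg(ploidy)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind%d", seq_len(nrow(calls)))
  }
  if (length(individual_ids) != nrow(calls)) {
    stop("genotype_matrix: individual_ids must match row count", call. = FALSE)
  }
  rownames(calls) <- individual_ids
  hi <- if (ploidy == "haploid") 1L else 2L
  if (length(calls) && !all(is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > hi) {
      stop(sprintf("genotype_matrix: %s calls must lie in 0..%d", ploidy, hi),
           call. = FALSE)
    }
  }
  if (!is.null(panel) && ncol(calls) != nrow(panel)) {
    stop(sprintf("genotype_matrix: %d columns but panel has %d SNPs",
                 ncol(calls), nrow(panel)), call. = FALSE)
  }
  structure(list(calls = calls, ploidy = ploidy,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%s)\n",
              nrow(x$calls), ncol(x$calls), x$ploidy))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Individual metadata table
#'
#' @param id character ids.
#' @param genetic_sex `"XX"`, `"XY"` or `"unassigned"`.
#' @param age_class `"adult"`, `"subadult"` or `"unknown"`.
#' @param mt_haplogroup,y_haplogroup haplogroup labels or `"unknown"`.
#'   A Y haplogroup may only be set when genetic sex is XY or unassigned.
#' @param population population label.
#' @return data frame of class `individual_meta`.
#' @export
individual_meta <- function(id, genetic_sex = "unassigned",
                            age_class = "unknown",
                            mt_haplogroup = "unknown",
                            y_haplogroup = "unknown",
                            population = "unknown") {
  n <- length(id)
  meta <- data.frame(
    id = as.character(id),
    genetic_sex = rep_len(as.character(genetic_sex), n),
    age_class = rep_len(as.character(age_class), n),
    mt_haplogroup = rep_len(as.character(mt_haplogroup), n),
    y_haplogroup = rep_len(as.character(y_haplogroup), n),
    population = rep_len(as.character(population), n),
    stringsAsFactors = FALSE
  )
  bad_sex <- !meta$genetic_sex %in% c("XX", "XY", "unassigned")
  if (any(bad_sex)) stop("individual_meta: genetic_sex must be XX, XY or unassigned",
                         call. = FALSE)
  bad_y <- meta$y_haplogroup != "unknown" & meta$genetic_sex == "XX"
  if (any(bad_y)) {
    stop(sprintf("individual_meta: XX individual(s) with a Y haplogroup: %s",
                 paste(meta$id[bad_y], collapse = ", ")), call. = FALSE)
  }
  class(meta) <- c("individual_meta", "data.frame")
  meta
}

# internal: index of an individual id in a genotype matrix, with clear error
match_individual <- function(geno, id) {
  i <- match(id, geno$individual_ids)
  if (is.na(i)) stop(sprintf("individual '%s' not found", id), call. = FALSE)
  i
}

# internal: save/restore RNG state around seeded operations so that package
# functions do not perturb the caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# internal: derive a stream-specific sub-seed from a master seed.
# Documented scheme: sub-seed = (seed * 48271 + stream) mod (2^31 - 1).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}
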