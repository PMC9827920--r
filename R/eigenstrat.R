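#' Read genotype data in EIGENSTRAT format
#'
#' Reads a `.geno`/`.snp`/`.ind` triple. The `.geno` file holds one row per
#' SNP and one character column per individual; characters are the count of
#' the snp-file's first-listed (ref) allele, with `9` for missing. Internally
#' calls are stored as alt-allele dosage (diploid: `alt = 2 - value`;
#' haploid: `alt = 1 - value`) with `NA` for missing. Ploidy is read from a
#' `<prefix>.ploidy` sidecar when present (written by [write_eigenstrat()]);
#' otherwise a file containing only `{0, 2, 9}` is treated as diploid, as is
#' any file containing a `1`.
#'
#' @param geno_path,snp_path,ind_path paths to the three EIGENSTRAT files.
#' @param ploidy optional `"haploid"` or `"diploid"` override.
#' @return list with elements `panel` (a [snp_panel()]), `genotypes`
#'   (a [genotype_matrix()]) and `meta` (an [individual_meta()] built from the
#'   `.ind` file; sex codes M/F mapped to XY/XX).
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = NULL) {
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("snp_id", "chromosome",
                                         "genetic_position",
                                         "physical_position",
                                         "ref_allele", "alt_allele"))
  panel <- snp_panel(snp$snp_id, snp$chromosome, snp$physical_position,
                     snp$genetic_position, snp$ref_allele, snp$alt_allele)

  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "sex", "population"))
  sex <- c(M = "XY", F = "XX", U = "unassigned")[ind$sex]
  sex[is.na(sex)] <- "unassigned"

  lines <- readLines(geno_path)
  if (length(lines) != nrow(panel)) {
    stop(sprintf("geno/snp dimension mismatch: %d geno rows vs %d snp rows",
                 length(lines), nrow(panel)), call. = FALSE)
  }
  n_ind <- nrow(ind)
  bad_len <- which(nchar(lines) != n_ind)
  if (n_ind > 0 && length(bad_len)) {
    stop(sprintf("geno/ind dimension mismatch at line %d: %d columns vs %d individuals",
                 bad_len[1], nchar(lines[bad_len[1]]), n_ind), call. = FALSE)
  }
  if (n_ind == 0) {
    calls <- matrix(NA_integer_, nrow = 0, ncol = nrow(panel))
  } else {
    # characters -> integer codes, one row per SNP
    raw <- matrix(utf8ToInt("0"), nrow = length(lines), ncol = n_ind)
    for (i in seq_along(lines)) raw[i, ] <- utf8ToInt(lines[i])
    vals <- raw - utf8ToInt("0")
    bad <- which(!(vals %in% c(0L, 1L, 2L, 9L)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(vals))
      stop(sprintf("illegal genotype character '%s' at geno line %d, column %d",
                   intToUtf8(raw[bad[1]]), rc[1], rc[2]), call. = FALSE)
    }
    if (is.null(ploidy)) {
      sidecar <- paste0(sub("\\.geno$", "", geno_path), ".ploidy")
      ploidy <- if (file.exists(sidecar)) {
        readLines(sidecar, n = 1)
      } else "diploid"
    }
    hi <- if (ploidy == "haploid") 1L else 2L
    if (any(vals > hi & vals != 9L)) {
      stop(sprintf("genotype value exceeds %s range in geno file", ploidy),
           call. = FALSE)
    }
    vals[vals == 9L] <- NA_integer_
    calls <- t(hi - vals)  # ref-count -> alt dosage; individuals in rows
  }
  geno <- genotype_matrix(calls, ploidy = if (is.null(ploidy)) "diploid" else ploidy,
                          individual_ids = ind$id, panel = panel)
  meta <- individual_meta(ind$id, genetic_sex = sex, population = ind$population)
  list(panel = panel, genotypes = geno, meta = meta)
}

#' Write genotype data in EIGENSTRAT format
#'
#' Inverse of [read_eigenstrat()]: writes `.geno` (ref-allele counts, `9` for
#' missing), `.snp`, `.ind`, and a `.ploidy` sidecar recording the ploidy
#' mode so that haploid data round-trip identically.
#'
#' @param panel a [snp_panel()].
#' @param genotypes a [genotype_matrix()] with `ncol == nrow(panel)`.
#' @param meta optional [individual_meta()]; populations and sexes are taken
#'   from it when supplied.
#' @param out_prefix path prefix for the four output files.
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_eigenstrat <- function(panel, genotypes, meta = NULL, out_prefix) {
  if (ncol(genotypes$calls) != nrow(panel)) {
    stop("write_eigenstrat: genotype columns must match panel SNPs", call. = FALSE)
  }
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop(sprintf("unwritable path: %s", dir), call. = FALSE)
  paths <- c(geno = paste0(out_prefix, ".geno"),
             snp = paste0(out_prefix, ".snp"),
             ind = paste0(out_prefix, ".ind"),
             ploidy = paste0(out_prefix, ".ploidy"))

  gpos <- panel$genetic_position
  gpos[is.na(gpos)] <- 0
  snp_tab <- data.frame(panel$snp_id, panel$chromosome, gpos,
                        panel$physical_position, panel$ref_allele,
                        panel$alt_allele)
  utils::write.table(snp_tab, paths["snp"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ids <- genotypes$individual_ids
  if (!is.null(meta)) {
    m <- meta[match(ids, meta$id), ]
    sex <- c(XY = "M", XX = "F", unassigned = "U")[m$genetic_sex]
    pop <- m$population
  } else {
    sex <- rep("U", length(ids))
    pop <- rep("unknown", length(ids))
  }
  utils::write.table(data.frame(ids, sex, pop), paths["ind"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  hi <- if (genotypes$ploidy == "haploid") 1L else 2L
  ref <- hi - t(genotypes$calls)   # SNPs in rows, ref-allele counts
  ref[is.na(ref)] <- 9L
  lines <- apply(ref, 1, paste0, collapse = "")
  if (nrow(panel) > 0 && length(ids) == 0) lines <- rep("", nrow(panel))
  writeLines(lines, paths["geno"])
  writeLines(genotypes$ploidy, paths["ploidy"])
  invisible(paths)
}

#' Read or write the individual metadata TSV
#'
#' Tab-separated with header `id, sex, age_class, mt_hg, y_hg, population`.
#' @param path file path.
#' @return [individual_meta()] data frame.
#' @export
read_individual_meta <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  individual_meta(tab$id, tab$sex, tab$age_class, tab$mt_hg, tab$y_hg,
                  tab$population)
}

#' @rdname read_individual_meta
#' @param meta an [individual_meta()] table.
#' @export
write_individual_meta <- function(meta, path) {
  out <- data.frame(id = meta$id, sex = meta$genetic_sex,
                    age_class = meta$age_class, mt_hg = meta$mt_haplogroup,
                    y_hg = meta$y_haplogroup, population = meta$population)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
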