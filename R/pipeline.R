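#' Run the kinship stage of the pipeline
#'
#' Chains the kinship analysis end to end: pseudo-haploid (or supplied
#' haploid) calls -> PMR for all pairs -> baseline from a reference panel ->
#' degree classification -> genotype-likelihood IBD coefficients for
#' first-degree pairs (when read counts are available) -> pedigree
#' enumeration. Deterministic given the seed.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{genotypes}{haploid [genotype_matrix()] of the study individuals.}
#'     \item{meta}{[individual_meta()] for the study individuals.}
#'     \item{panel}{optional [snp_panel()] (for autosome filtering).}
#'     \item{reference}{haploid [genotype_matrix()] of an unrelated
#'       reference panel, or a numeric baseline `b`.}
#'     \item{read_counts}{optional `read_counts` for the study individuals.}
#'     \item{freqs}{optional per-site allele frequencies for the IBD model
#'       (defaults to pooled frequencies of the reference panel).}
#'     \item{base_error}{per-read error rate for genotype likelihoods
#'       (default 0.01).}
#'     \item{max_latent, max_generations}{pedigree search bounds.}
#'     \item{seed}{master seed.}
#'   }
#' @return list of class `kinship_report`: `kinship_table`, `baseline`,
#'   `first_degree_types`, `pedigrees`, `provenance`.
#' @export
run_kinship_pipeline <- function(config) {
  stopifnot(!is.null(config$genotypes), !is.null(config$meta),
            !is.null(config$seed))
  geno <- config$genotypes
  meta <- config$meta
  ids <- meta$id
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("kinship pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (length(ids) < 2) {
    return(structure(list(kinship_table = NULL, baseline = NULL,
                          first_degree_types = NULL, pedigrees = NULL,
                          provenance = pipeline_provenance(config)),
                     class = "kinship_report"))
  }
  baseline <- stage("baseline", {
    if (is.numeric(config$reference)) list(b = config$reference)
    else background_pmr(config$reference, panel = config$panel)
  })
  kin <- stage("pmr_classify", {
    classify_all_pairs(geno, baseline$b, ids = ids, panel = config$panel)
  })
  first_types <- NULL
  if (!is.null(config$read_counts)) {
    first_types <- stage("ibd_coefficients", {
      freqs <- config$freqs
      if (is.null(freqs)) {
        pooled <- group_frequencies(config$reference,
                                    rep("ref", length(config$reference$individual_ids)))
        freqs <- pooled$freq[, 1]
      }
      err <- config$base_error %||% 0.01
      first <- kin[kin$degree == "first", , drop = FALSE]
      rows <- lapply(seq_len(nrow(first)), function(r) {
        i1 <- first$id1[r]; i2 <- first$id2[r]
        gl1 <- genotype_likelihoods(config$read_counts$ref[i1, ],
                                    config$read_counts$alt[i1, ], err)
        gl2 <- genotype_likelihoods(config$read_counts$ref[i2, ],
                                    config$read_counts$alt[i2, ], err)
        ibd <- estimate_ibd_coefficients(gl1, gl2, freqs)
        cls <- disambiguate_first_degree(ibd,
                                         meta$age_class[match(c(i1, i2), meta$id)])
        data.frame(id1 = i1, id2 = i2, k0 = ibd$k0, k1 = ibd$k1, k2 = ibd$k2,
                   kappa = ibd$kappa, type = cls$type,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  peds <- stage("pedigree_enumeration", {
    enumerate_pedigrees(meta, kin, first_degree_types = first_types,
                        max_latent = config$max_latent %||% 4,
                        max_generations = config$max_generations %||% 3)
  })
  structure(list(kinship_table = kin, baseline = baseline,
                 first_degree_types = first_types, pedigrees = peds,
                 provenance = pipeline_provenance(config)),
            class = "kinship_report")
}

#' Run the population-affinity stage of the pipeline
#'
#' Computes the outgroup-f3 affinity ranking of a target against candidate
#' populations, an f4 symmetry scan, qpWave cladality tests and qpAdm
#' admixture models with smallest-submodel reduction: sources whose removal
#' does not significantly worsen the fit (nested model still fits at
#' `p > reduce_p`) are dropped, smallest model retained.
#'
#' @param config list with elements `freqs` (a [group_frequencies()] result
#'   or frequency matrix), `block` (from [assign_jackknife_blocks()]),
#'   `outgroup`, `target`, `candidates` (for f3/f4), `reference` (the
#'   population the target is compared to in f4/qpWave), `sources`,
#'   `rights` (for qpAdm), `reduce_p` (default 0.05), `seed`.
#' @return list of class `popgen_report` with `f3_ranking`, `f4_scan`,
#'   `qpwave`, `qpadm_full`, `qpadm_reduced`, `provenance`.
#' @export
run_popgen_pipeline <- function(config) {
  freqs <- config$freqs
  block <- config$block
  reduce_p <- config$reduce_p %||% 0.05
  f3_ranking <- NULL
  if (!is.null(config$candidates)) {
    rows <- lapply(config$candidates, function(pop) {
      r <- f3_outgroup(freqs, config$outgroup, config$target, pop, block)
      data.frame(population = pop, f3 = r$estimate, se = r$se, z = r$z,
                 n_snps = r$n_snps, stringsAsFactors = FALSE)
    })
    f3_ranking <- do.call(rbind, rows)
    f3_ranking <- f3_ranking[order(-f3_ranking$f3), ]
    rownames(f3_ranking) <- NULL
  }
  f4_scan <- NULL
  if (!is.null(config$candidates) && !is.null(config$reference)) {
    rows <- lapply(setdiff(config$candidates, config$reference), function(pop) {
      r <- f4(freqs, config$outgroup, pop, config$target, config$reference,
              block)
      data.frame(population = pop, f4 = r$estimate, se = r$se, z = r$z,
                 significant = abs(r$z) >= 3, stringsAsFactors = FALSE)
    })
    f4_scan <- do.call(rbind, rows)
  }
  qpw <- NULL
  if (!is.null(config$reference)) {
    qpw <- qpwave_rank_test(freqs, c(config$target, config$reference),
                            config$rights, block, rank = 0)
  }
  qpadm_full <- qpadm_reduced <- NULL
  if (!is.null(config$sources)) {
    qpadm_full <- qpadm_weights(freqs, config$target, config$sources,
                                config$rights, block)
    # smallest submodel: greedily drop the source whose removal leaves the
    # best-fitting nested model, while that model still fits
    cur <- config$sources
    fit <- qpadm_full
    repeat {
      if (length(cur) <= 1) break
      cand <- lapply(seq_along(cur), function(i) {
        qpadm_weights(freqs, config$target, cur[-i], config$rights, block)
      })
      ps <- vapply(cand, `[[`, numeric(1), "p_value")
      best <- which.max(ps)
      if (ps[best] > reduce_p) {
        cur <- cur[-best]
        fit <- cand[[best]]
      } else break
    }
    qpadm_reduced <- fit
  }
  structure(list(f3_ranking = f3_ranking, f4_scan = f4_scan, qpwave = qpw,
                 qpadm_full = qpadm_full, qpadm_reduced = qpadm_reduced,
                 provenance = pipeline_provenance(config)),
            class = "popgen_report")
}

#' Write a pipeline report as JSON
#'
#' Serializes a `kinship_report` or `popgen_report` (tables as arrays of
#' records, pedigrees as trio tables) for machine consumption alongside the
#' TSV outputs.
#'
#' @param report a report from [run_kinship_pipeline()] or
#'   [run_popgen_pipeline()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- report[!vapply(report, is.null, logical(1))]
  if (!is.null(out$pedigrees)) {
    peds <- out$pedigrees
    out$pedigrees <- list(
      near_miss = peds$near_miss,
      n_searched = peds$n_searched,
      alternates = lapply(peds$reports, function(r) {
        list(score = r$score, n_constraints = r$n_constraints,
             violations = r$violations,
             trios = render_pedigree(r$pedigree)$trios)
      }),
      co_maximal = peds$co_maximal)
  }
  if (!is.null(out$baseline) && inherits(out$baseline, "pmr_baseline")) {
    out$baseline <- out$baseline[c("b", "n_pairs", "min", "max", "iqr")]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

pipeline_provenance <- function(config) {
  cfg <- config[setdiff(names(config), c("genotypes", "reference",
                                         "read_counts", "freqs"))]
  list(package_version = as.character(utils::packageVersion("paleokin")),
       seed = config$seed,
       config_hash = sum(utf8ToInt(paste(utils::capture.output(utils::str(cfg)),
                                         collapse = ""))))
}

#' Command-line interface
#'
#' Thin dispatcher over the package's main operations, used by the
#' `inst/exec/paleokin` script. Subcommands: `mni <counts.tsv>`,
#' `sex <coverage.tsv>` (columns id, autosome, x, y), `kinship
#' <prefix> <baseline>` (EIGENSTRAT prefix plus a numeric baseline
#' mismatch rate). Prints tab-separated results to stdout.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success, 2 on usage error).
#' @export
paleokin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: paleokin <mni|sex|kinship> ...\n",
        "  mni <counts.tsv>            assemblage MNI from element counts\n",
        "  sex <coverage.tsv>          genetic sex from depth ratios\n",
        "  kinship <prefix> <baseline> degree calls from EIGENSTRAT data\n",
        sep = "")
    invisible(2L)
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  if (cmd == "mni" && length(args) >= 2) {
    res <- total_mni(read_element_counts(args[2]))
    utils::write.table(res$per_element, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat(sprintf("adult\t%d\nsubadult\t%d\ntotal\t%d\n", res$adult,
                res$subadult, res$total))
    invisible(0L)
  } else if (cmd == "sex" && length(args) >= 2) {
    tab <- utils::read.table(args[2], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    res <- assign_genetic_sex(coverage_summary(tab$id, tab$autosome, tab$x,
                                               tab$y))
    utils::write.table(res, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(0L)
  } else if (cmd == "kinship" && length(args) >= 3) {
    es <- read_eigenstrat(paste0(args[2], ".geno"), paste0(args[2], ".snp"),
                          paste0(args[2], ".ind"))
    tab <- classify_all_pairs(es$genotypes, as.numeric(args[3]),
                              panel = es$panel)
    utils::write.table(tab, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(0L)
  } else usage()
}
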