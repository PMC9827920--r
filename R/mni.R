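#' Skeletal element count table
#'
#' One row per (element, age class) with counts of left, right and unsided
#' specimens. Unpaired midline bones (frontal, occipital, ...) go in the
#' `unsided` column. Elements unreliable to side (ribs, vertebrae,
#' phalanges) should be excluded by the data preparer.
#'
#' @param element,age_class,left,right,unsided per-row vectors; age class
#'   must be `"adult"` or `"subadult"`.
#' @return data frame of class `element_counts`.
#' @export
element_counts <- function(element, age_class, left = 0, right = 0,
                           unsided = 0) {
  n <- length(element)
  tab <- data.frame(element = as.character(element),
                    age_class = as.character(age_class),
                    left = rep_len(as.integer(left), n),
                    right = rep_len(as.integer(right), n),
                    unsided = rep_len(as.integer(unsided), n),
                    stringsAsFactors = FALSE)
  if (any(!tab$age_class %in% c("adult", "subadult"))) {
    stop("element_counts: age_class must be adult or subadult", call. = FALSE)
  }
  if (any(as.matrix(tab[, c("left", "right", "unsided")]) < 0)) {
    stop("element_counts: counts must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("element", "age_class")])) {
    stop("element_counts: duplicate (element, age_class) rows", call. = FALSE)
  }
  class(tab) <- c("element_counts", "data.frame")
  tab
}

#' @rdname element_counts
#' @param path TSV with header `element, age_class, left, right, unsided`.
#' @export
read_element_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  element_counts(tab$element, tab$age_class, tab$left, tab$right, tab$unsided)
}

#' Per-element minimum number of individuals
#'
#' For one skeletal element, the MNI contribution per age class is the
#' greatest of the left, right and unsided counts (each specimen of one
#' side must belong to a different individual); the combined value sums the
#' age classes, since adults and subadults cannot share a skeleton.
#'
#' @param table an [element_counts()] table.
#' @param element element name.
#' @return list with `per_age_class` (named integer vector) and `combined`.
#' @export
per_element_mni <- function(table, element) {
  rows <- table[table$element == element, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("unknown element '%s'", element), call. = FALSE)
  per <- vapply(seq_len(nrow(rows)), function(i) {
    max(rows$left[i], rows$right[i], rows$unsided[i])
  }, integer(1))
  names(per) <- rows$age_class
  list(per_age_class = per, combined = sum(per))
}

#' Assemblage minimum number of individuals
#'
#' Per age class, the assemblage MNI is the maximum of the per-element
#' values over all elements (the maxima may come from different elements);
#' the total is the sum of the age-class MNIs.
#'
#' @param table an [element_counts()] table.
#' @return list with `adult`, `subadult`, `total` and `per_element` (data
#'   frame of per-row MNI values with the combined column).
#' @export
total_mni <- function(table) {
  if (!nrow(table)) stop("total_mni: empty element table", call. = FALSE)
  elements <- unique(table$element)
  per <- lapply(elements, function(e) per_element_mni(table, e))
  adult <- max(0L, vapply(per, function(x)
    max(0L, x$per_age_class[names(x$per_age_class) == "adult"]), integer(1)))
  subadult <- max(0L, vapply(per, function(x)
    max(0L, x$per_age_class[names(x$per_age_class) == "subadult"]), integer(1)))
  per_tab <- data.frame(element = elements,
                        adult = vapply(per, function(x)
                          max(0L, x$per_age_class[names(x$per_age_class) == "adult"]),
                          integer(1)),
                        subadult = vapply(per, function(x)
                          max(0L, x$per_age_class[names(x$per_age_class) == "subadult"]),
                          integer(1)),
                        mni = vapply(per, `[[`, integer(1), "combined"),
                        stringsAsFactors = FALSE)
  list(adult = adult, subadult = subadult, total = adult + subadult,
       per_element = per_tab)
}
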