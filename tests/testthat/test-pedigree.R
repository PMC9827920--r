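# small pedigrees used throughout
ped_po <- function() pedigree(c("p", "c"), c("M", "M"),
                              father = c(NA, "p"))
ped_fs <- function() pedigree(c("f", "m", "a", "b"), c("M", "F", "M", "F"),
                              father = c(NA, NA, "f", "f"),
                              mother = c(NA, NA, "m", "m"))
ped_hs <- function() pedigree(c("f", "m1", "m2", "a", "b"),
                              c("M", "F", "F", "M", "M"),
                              father = c(NA, NA, NA, "f", "f"),
                              mother = c(NA, NA, NA, "m1", "m2"))

test_that("expected kinship matches Mendelian constants for standard classes", {
  po <- expected_kinship(ped_po(), "p", "c")
  expect_equal(c(po$kappa, po$k0, po$k1, po$k2), c(0.25, 0, 1, 0))
  expect_identical(po$degree, "first")

  fs <- expected_kinship(ped_fs(), "a", "b")
  expect_equal(c(fs$kappa, fs$k0, fs$k1, fs$k2), c(0.25, 0.25, 0.5, 0.25))

  hs <- expected_kinship(ped_hs(), "a", "b")
  expect_equal(c(hs$kappa, hs$k0, hs$k1, hs$k2), c(0.125, 0.5, 0.5, 0))
  expect_identical(hs$degree, "second")

  # grandparent and avuncular also land in the second-degree class
  gp <- pedigree(c("g", "f", "c"), c("M", "M", "F"),
                 father = c(NA, "g", "f"))
  expect_equal(expected_kinship(gp, "g", "c")$kappa, 0.125)
  expect_equal(expected_kinship(gp, "g", "c")$k2, 0)

  # first cousins: third degree
  fc <- pedigree(c("g1", "g2", "f1", "f2", "c1", "c2"),
                 c("M", "F", "M", "M", "M", "M"),
                 father = c(NA, NA, "g1", "g1", "f1", "f2"),
                 mother = c(NA, NA, "g2", "g2", NA, NA))
  expect_equal(expected_kinship(fc, "c1", "c2")$kappa, 1 / 16)
  expect_identical(expected_kinship(fc, "c1", "c2")$degree, "third")

  expect_error(expected_kinship(ped_po(), "p", "zz"), "both ids")
  # inbred pedigrees are rejected
  inbred <- pedigree(c("f", "m", "a", "b", "x"), c("M", "F", "M", "F", "M"),
                     father = c(NA, NA, "f", "f", "a"),
                     mother = c(NA, NA, "m", "m", "b"))
  expect_error(expected_kinship(inbred, "x", "a"), "inbred")
})

test_that("expected kinship agrees with independent gene-dropping simulation", {
  # drop uniquely-labelled founder alleles through the pedigree and measure
  # the probability that one random allele from each individual is IBD
  gene_drop_kappa <- function(ped, a, b, n_loci = 2e4, seed = 1) {
    set.seed(seed)
    ids <- ped$id
    al1 <- matrix(NA_integer_, length(ids), n_loci, dimnames = list(ids, NULL))
    al2 <- al1
    next_label <- 1L
    depth <- order(vapply(ids, function(i) {
      d <- 0L; cur <- i
      repeat {
        j <- match(cur, ped$id)
        if (is.na(ped$father[j]) && is.na(ped$mother[j])) break
        cur <- if (!is.na(ped$father[j])) ped$father[j] else ped$mother[j]
        d <- d + 1L
      }
      d
    }, integer(1)))
    # process so parents come first: repeat sweeps until filled
    remaining <- ids
    while (length(remaining)) {
      for (id in remaining) {
        j <- match(id, ped$id)
        fa <- ped$father[j]; mo <- ped$mother[j]
        fa_ok <- is.na(fa) || !anyNA(al1[fa, 1])
        mo_ok <- is.na(mo) || !anyNA(al1[mo, 1])
        if (!fa_ok || !mo_ok) next
        if (is.na(fa)) {
          al1[id, ] <- next_label; next_label <- next_label + 1L
        } else {
          pick <- runif(n_loci) < 0.5
          al1[id, ] <- ifelse(pick, al1[fa, ], al2[fa, ])
        }
        if (is.na(mo)) {
          al2[id, ] <- next_label; next_label <- next_label + 1L
        } else {
          pick <- runif(n_loci) < 0.5
          al2[id, ] <- ifelse(pick, al1[mo, ], al2[mo, ])
        }
        remaining <- setdiff(remaining, id)
      }
    }
    pa <- ifelse(runif(n_loci) < 0.5, al1[a, ], al2[a, ])
    pb <- ifelse(runif(n_loci) < 0.5, al1[b, ], al2[b, ])
    mean(pa == pb)
  }
  cases <- list(list(ped_po(), "p", "c"), list(ped_fs(), "a", "b"),
                list(ped_hs(), "a", "b"))
  for (cs in cases) {
    kappa <- expected_kinship(cs[[1]], cs[[2]], cs[[3]])$kappa
    khat <- gene_drop_kappa(cs[[1]], cs[[2]], cs[[3]])
    expect_lt(abs(khat - kappa), 3 * sqrt(kappa * (1 - kappa) / 2e4))
  }
})

test_that("pedigree rendering round-trips through the trio table", {
  fam <- family_test_pedigree()
  spec <- fam$spec
  ped <- pedigree(spec$id, spec$sex, spec$father, spec$mother,
                  observed = spec$id %in% fam$observed,
                  mt_hg = spec$mt_hg, y_hg = spec$y_hg)
  out <- render_pedigree(ped)
  expect_equal(nrow(out$trios), sum(!is.na(ped$father) | !is.na(ped$mother)))
  back <- trios_to_pedigree(out$trios,
                            nodes = ped[, c("id", "sex", "observed",
                                            "mt_hg", "y_hg")])
  ord <- match(ped$id, back$id)
  expect_identical(back$father[ord], ped$father)
  expect_identical(back$mother[ord], ped$mother)
  # identical expected kinship after the round trip
  for (pr in list(c("FTH", "SON"), c("UNC", "DAU"), c("REL", "FTH"))) {
    expect_equal(expected_kinship(back, pr[1], pr[2])$kappa,
                 expected_kinship(ped, pr[1], pr[2])$kappa)
  }
  # quartet reduces to two trio rows; empty pedigree to none
  quartet <- ped_fs()
  expect_equal(nrow(render_pedigree(quartet)$trios), 2L)
  lone <- pedigree("solo", "M")
  expect_equal(nrow(render_pedigree(lone)$trios), 0L)
})

test_that("a quartet degree pattern yields the couple-plus-two-children pedigree", {
  meta <- individual_meta(c("F1", "M1", "C1", "C2"),
                          genetic_sex = c("XY", "XX", "XY", "XX"),
                          age_class = c("adult", "adult", "adult", "subadult"),
                          mt_haplogroup = c("h1", "h2", "h2", "h2"),
                          y_haplogroup = c("y1", "unknown", "y1", "unknown"))
  prs <- utils::combn(meta$id, 2)
  deg <- data.frame(id1 = prs[1, ], id2 = prs[2, ],
                    degree = c("unrelated", "first", "first", "first",
                               "first", "first"),
                    stringsAsFactors = FALSE)
  fdt <- data.frame(id1 = c("F1", "F1", "M1", "M1", "C1"),
                    id2 = c("C1", "C2", "C1", "C2", "C2"),
                    type = c("parent_offspring", "parent_offspring",
                             "parent_offspring", "parent_offspring",
                             "full_sibling"), stringsAsFactors = FALSE)
  res <- enumerate_pedigrees(meta, deg, first_degree_types = fdt)
  expect_gt(length(res$reports), 0)
  top <- res$reports[[res$co_maximal[1]]]$pedigree
  expect_identical(sort(c(top$father[match(c("C1", "C2"), top$id)],
                          top$mother[match(c("C1", "C2"), top$id)])),
                   c("F1", "F1", "M1", "M1"))
  # all co-maximal pedigrees are the quartet structure
  for (i in res$co_maximal) {
    p <- res$reports[[i]]$pedigree
    expect_equal(expected_kinship(p, "C1", "C2")$k2, 0.25)
  }
})

test_that("a first-degree relative of the mother keeps both orientations, mt ranks child first", {
  # the maternal-relative pattern: X first degree to the mother, second to
  # both children, unrelated to the father; X shares the children's mt
  meta <- individual_meta(c("F1", "M1", "C1", "C2", "X5"),
                          genetic_sex = c("XY", "XX", "XY", "XX", "XY"),
                          age_class = "adult",
                          mt_haplogroup = c("h1", "h2", "h2", "h2", "h2"),
                          y_haplogroup = c("y1", "unknown", "y1", "unknown",
                                           "y9"))
  prs <- utils::combn(meta$id, 2)
  degmap <- c("F1 M1" = "unrelated", "F1 C1" = "first", "F1 C2" = "first",
              "F1 X5" = "unrelated", "M1 C1" = "first", "M1 C2" = "first",
              "M1 X5" = "first", "C1 C2" = "first", "C1 X5" = "second",
              "C2 X5" = "second")
  deg <- data.frame(id1 = prs[1, ], id2 = prs[2, ],
                    degree = unname(degmap[paste(prs[1, ], prs[2, ])]),
                    stringsAsFactors = FALSE)
  res <- enumerate_pedigrees(meta, deg)
  expect_gt(length(res$reports), 1)
  is_child_of_m <- vapply(res$reports, function(r) {
    p <- r$pedigree
    identical(p$mother[match("X5", p$id)], "M1")
  }, logical(1))
  is_parent_of_m <- vapply(res$reports, function(r) {
    p <- r$pedigree
    identical(p$father[match("M1", p$id)], "X5")
  }, logical(1))
  # both orientations are retained in the report list
  expect_true(any(is_child_of_m))
  expect_true(any(is_parent_of_m))
  # mt consistency ranks maternal-line placements (X5 sharing the
  # children's maternal line) above the parent-of-mother option
  mt_linked <- vapply(res$reports, function(r) {
    p <- r$pedigree
    line <- function(id) {
      out <- character(0)
      while (!is.na(id)) { out <- c(out, id); id <- p$mother[match(id, p$id)] }
      out
    }
    length(intersect(line("X5"), line("C1"))) > 0
  }, logical(1))
  expect_true(mt_linked[1])
  expect_lt(max(which(mt_linked)), min(which(!mt_linked)))
})

test_that("a third-degree paternal pattern places the relative on the father's line", {
  fam <- family_test_pedigree()
  res <- enumerate_pedigrees(fam$meta, family_degrees(),
                             first_degree_types = family_first_degree_types())
  expect_gt(length(res$reports), 0)
  # every co-maximal pedigree joins REL and FTH through an unbroken male line
  paternal_chain <- function(ped, id) {
    out <- character(0)
    while (!is.na(id)) { out <- c(out, id); id <- ped$father[match(id, ped$id)] }
    out
  }
  for (i in res$co_maximal) {
    p <- res$reports[[i]]$pedigree
    expect_gt(length(intersect(paternal_chain(p, "REL"),
                               paternal_chain(p, "FTH"))), 0)
    # and the maternal-relative is placed as the mother's son (mt-preferred)
    expect_identical(p$mother[match("UNC", p$id)], "MTH")
  }
  # the true simulated structure is among the co-maximal alternates:
  # REL a paternal half-uncle, i.e. REL shares a single parent with FTH's
  # father
  has_true <- any(vapply(res$co_maximal, function(i) {
    p <- res$reports[[i]]$pedigree
    pf <- p$father[match("FTH", p$id)]
    if (is.na(pf)) return(FALSE)
    gpa <- p$father[match(pf, p$id)]
    !is.na(gpa) && identical(p$father[match("REL", p$id)], gpa)
  }, logical(1)))
  expect_true(has_true)
})

test_that("enumeration recovers random ground-truth pedigrees within bounds", {
  # ground-truth pedigrees built from the simulator's spec; observed degree
  # matrices derived by path counting; the truth must always be among the
  # returned set
  cases <- list(
    list(spec = pedigree_spec(id = c("f", "m", "a", "b"),
                              sex = c("M", "F", "M", "F"),
                              father = c(NA, NA, "f", "f"),
                              mother = c(NA, NA, "m", "m"),
                              generation = c(1, 1, 2, 2)),
         observed = c("f", "m", "a", "b")),
    list(spec = pedigree_spec(id = c("g", "gm", "f", "m", "c", "u"),
                              sex = c("M", "F", "M", "F", "M", "M"),
                              father = c(NA, NA, "g", NA, "f", "g"),
                              mother = c(NA, NA, "gm", NA, "m", "gm"),
                              generation = c(1, 1, 2, 2, 3, 2)),
         observed = c("g", "m", "c", "u")))
  for (cs in cases) {
    spec <- cs$spec
    ped <- pedigree(spec$id, spec$sex, spec$father, spec$mother,
                    observed = spec$id %in% cs$observed)
    prs <- utils::combn(cs$observed, 2)
    deg <- data.frame(id1 = prs[1, ], id2 = prs[2, ],
                      degree = vapply(seq_len(ncol(prs)), function(k)
                        expected_kinship(ped, prs[1, k], prs[2, k])$degree,
                        character(1)), stringsAsFactors = FALSE)
    meta <- individual_meta(cs$observed,
                            genetic_sex = ifelse(spec$sex[match(cs$observed,
                                                                spec$id)] == "M",
                                                 "XY", "XX"))
    res <- enumerate_pedigrees(meta, deg)
    expect_gt(length(res$reports), 0)
    # every returned pedigree reproduces the observed degree matrix
    for (r in res$reports) {
      for (k in seq_len(ncol(prs))) {
        expect_identical(expected_kinship(r$pedigree, prs[1, k],
                                          prs[2, k])$degree, deg$degree[k])
      }
    }
  }
})
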