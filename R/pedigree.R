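#' Pedigree container for inference
#'
#' A directed parent-to-child graph. Unlike the strict simulation
#' [pedigree_spec()], an inference pedigree allows a node to have 0, 1 or 2
#' recorded parents: a missing parent stands for an implicit, unique,
#' unrelated founder. This keeps the number of explicit latent connectors
#' needed for distant (2nd/3rd-degree) links small. Nodes carry sex
#' (`"M"`, `"F"` or `NA`), an observed/latent flag and optional mt/Y
#' haplogroup annotations.
#'
#' @param id,sex,father,mother,observed per-node vectors (`NA` father/mother
#'   for an unrecorded parent).
#' @param mt_hg,y_hg optional haplogroup labels (`NA` = unknown).
#' @return data frame of class `pedigree`.
#' @export
pedigree <- function(id, sex = NA, father = NA, mother = NA, observed = TRUE,
                     mt_hg = NA, y_hg = NA) {
  n <- length(id)
  ped <- data.frame(id = as.character(id), sex = rep_len(as.character(sex), n),
                    father = rep_len(as.character(father), n),
                    mother = rep_len(as.character(mother), n),
                    observed = rep_len(as.logical(observed), n),
                    mt_hg = rep_len(as.character(mt_hg), n),
                    y_hg = rep_len(as.character(y_hg), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("pedigree: duplicate ids", call. = FALSE)
  for (col in c("father", "mother")) {
    known <- !is.na(ped[[col]])
    if (any(known & !ped[[col]] %in% ped$id)) {
      stop("pedigree: parent id not in pedigree", call. = FALSE)
    }
  }
  # acyclicity via depth computation (errors on a cycle)
  ped_depths(ped)
  fa_sex <- ped$sex[match(ped$father, ped$id)]
  mo_sex <- ped$sex[match(ped$mother, ped$id)]
  if (any(fa_sex == "F", na.rm = TRUE) || any(mo_sex == "M", na.rm = TRUE)) {
    stop("pedigree: parents of a node must have different (correct) sexes",
         call. = FALSE)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# internal light-weight constructor used by the simulator (already validated)
ped_nodes <- function(id, father, mother, sex) {
  data.frame(id = as.character(id), father = as.character(father),
             mother = as.character(mother), sex = as.character(sex),
             stringsAsFactors = FALSE)
}

# depth of each node = 1 + max(parent depths); founders at 0. Errors on cycles.
ped_depths <- function(ped) {
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  names(depth) <- ped$id
  resolve <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (ped$id[i] %in% seen) stop("pedigree: cycle detected", call. = FALSE)
    seen <- c(seen, ped$id[i])
    d <- 0L
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p)) d <- max(d, resolve(match(p, ped$id), seen) + 1L)
    }
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) resolve(i, character(0))
  depth
}

# recursive kinship coefficient phi(a, b); missing parents contribute 0.
# Non-inbred pedigrees only (phi(x,x) = 1/2).
ped_kinship <- function(ped, a, b, depth = ped_depths(ped),
                        memo = new.env(parent = emptyenv())) {
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- paste(sort(c(x, y)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      0.5
    } else {
      # recurse on the deeper node; it cannot be an ancestor of the other
      if (depth[x] < depth[y]) { tmp <- x; x <- y; y <- tmp }
      i <- match(x, ped$id)
      if (depth[x] == 0L) 0 else {
        (phi(ped$father[i], y) + phi(ped$mother[i], y)) / 2
      }
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

# detect inbreeding: any node whose recorded parents are related
ped_is_inbred <- function(ped) {
  depth <- ped_depths(ped)
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ped))) {
    if (!is.na(ped$father[i]) && !is.na(ped$mother[i]) &&
        ped_kinship(ped, ped$father[i], ped$mother[i], depth, memo) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

# kappa and (k0,k1,k2) for a non-inbred pair via parental kinships:
#   k2 = phi(fa,fb) phi(ma,mb) + phi(fa,mb) phi(ma,fb)
#   k1 = 4 kappa - 2 k2;  k0 = 1 - k1 - k2
ped_relatedness <- function(ped, a, b, depth = ped_depths(ped),
                            memo = new.env(parent = emptyenv())) {
  kappa <- ped_kinship(ped, a, b, depth, memo)
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  k2 <- ped_kinship(ped, ped$father[ia], ped$father[ib], depth, memo) *
    ped_kinship(ped, ped$mother[ia], ped$mother[ib], depth, memo) +
    ped_kinship(ped, ped$father[ia], ped$mother[ib], depth, memo) *
    ped_kinship(ped, ped$mother[ia], ped$father[ib], depth, memo)
  k1 <- 4 * kappa - 2 * k2
  list(kappa = kappa, k0 = 1 - k1 - k2, k1 = k1, k2 = k2)
}

#' Expected kinship of a pair under a pedigree
#'
#' Computes the kinship coefficient by recursive path counting over parents
#' and derives the IBD-sharing probabilities (k0, k1, k2) from parental
#' kinships; valid for non-inbred pedigrees (inbred ones are rejected).
#'
#' @param ped a [pedigree()].
#' @param id1,id2 member ids.
#' @return list with `kappa`, `k0`, `k1`, `k2` and `degree`
#'   (`"identical"`, `"first"`, `"second"`, `"third"` or `"unrelated"`;
#'   relationships beyond third degree map to `"unrelated"`).
#' @export
expected_kinship <- function(ped, id1, id2) {
  if (!id1 %in% ped$id || !id2 %in% ped$id) {
    stop("expected_kinship: both ids must be in the pedigree", call. = FALSE)
  }
  if (ped_is_inbred(ped)) {
    stop("expected_kinship: inbred pedigrees are not supported", call. = FALSE)
  }
  res <- ped_relatedness(ped, id1, id2)
  res$degree <- degree_from_kappa(res$kappa)
  res
}

# kappa -> degree class, midpoint boundaries; >3rd degree is "unrelated"
degree_from_kappa <- function(kappa) {
  cuts <- c(3 / 8, 3 / 16, 3 / 32, 3 / 64)
  labels <- c("identical", "first", "second", "third", "unrelated")
  labels[findInterval(-kappa, -cuts) + 1L]
}

#' Render a pedigree as text and a trio table
#'
#' The trio table (`child`, `father`, `mother`) together with the node
#' annotations round-trips to an identical pedigree via [trios_to_pedigree()].
#' Ordering is deterministic: by generation depth, then id.
#'
#' @param ped a [pedigree()].
#' @return list with `text` (character vector of diagram lines) and `trios`
#'   (data frame with one row per node that has at least one recorded
#'   parent).
#' @export
render_pedigree <- function(ped) {
  depth <- ped_depths(ped)
  ord <- order(depth, ped$id)
  lines <- character(0)
  for (g in sort(unique(depth))) {
    members <- ped$id[ord][depth[ord] == g]
    desc <- vapply(members, function(m) {
      i <- match(m, ped$id)
      par <- c(ped$father[i], ped$mother[i])
      par <- par[!is.na(par)]
      lab <- if (length(par)) paste0(m, " <- (", paste(par, collapse = " x "), ")")
      else m
      if (!ped$observed[i]) lab <- paste0("[", lab, "]")
      lab
    }, character(1))
    lines <- c(lines, sprintf("G%d: %s", g + 1L, paste(desc, collapse = "  ")))
  }
  has_par <- !is.na(ped$father) | !is.na(ped$mother)
  trios <- ped[has_par, c("id", "father", "mother")]
  names(trios)[1] <- "child"
  trios <- trios[order(depth[has_par], trios$child), ]
  rownames(trios) <- NULL
  list(text = lines, trios = trios)
}

#' @rdname render_pedigree
#' @param trios trio table as returned by [render_pedigree()].
#' @param nodes data frame of node annotations (`id`, `sex`, `observed`,
#'   `mt_hg`, `y_hg`); defaults cover ids appearing only in the trio table.
#' @export
trios_to_pedigree <- function(trios, nodes = NULL) {
  ids <- unique(c(trios$child, trios$father, trios$mother,
                  if (!is.null(nodes)) nodes$id))
  ids <- ids[!is.na(ids)]
  ped <- data.frame(id = ids, sex = NA_character_,
                    father = trios$father[match(ids, trios$child)],
                    mother = trios$mother[match(ids, trios$child)],
                    observed = TRUE, mt_hg = NA_character_,
                    y_hg = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    j <- match(ped$id, nodes$id)
    for (col in intersect(c("sex", "observed", "mt_hg", "y_hg"), names(nodes))) {
      ped[[col]] <- ifelse(is.na(j), ped[[col]], nodes[[col]][j])
    }
  }
  pedigree(ped$id, ped$sex, ped$father, ped$mother, ped$observed,
           ped$mt_hg, ped$y_hg)
}

# ---------------------------------------------------------------------------
# Pedigree enumeration
# ---------------------------------------------------------------------------

# number of generation levels spanned by observed members, using a proper
# leveling (child level = parent level + 1, spouses aligned through their
# children). Components are leveled independently; the span is the largest
# per-component observed span. Returns Inf for generation-inconsistent
# structures (someone occupying two levels at once).
ped_generation_span <- function(ped) {
  n <- nrow(ped)
  lev <- stats::setNames(rep(NA_real_, n), ped$id)
  span <- 0
  for (start in seq_len(n)) {
    if (!is.na(lev[ped$id[start]])) next
    lev[ped$id[start]] <- 0
    queue <- ped$id[start]
    comp <- character(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      i <- match(cur, ped$id)
      for (p in c(ped$father[i], ped$mother[i])) {
        if (is.na(p)) next
        want <- lev[cur] - 1
        if (is.na(lev[p])) { lev[p] <- want; queue <- c(queue, p) }
        else if (lev[p] != want) return(Inf)
      }
      kids <- ped$id[which((!is.na(ped$father) & ped$father == cur) |
                             (!is.na(ped$mother) & ped$mother == cur))]
      for (k in kids) {
        want <- lev[cur] + 1
        if (is.na(lev[k])) { lev[k] <- want; queue <- c(queue, k) }
        else if (lev[k] != want) return(Inf)
      }
    }
    obs_l <- lev[comp[ped$observed[match(comp, ped$id)]]]
    if (length(obs_l)) span <- max(span, max(obs_l) - min(obs_l) + 1)
  }
  span
}

# maternal-line ancestors of a node (self included)
maternal_line <- function(ped, id) {
  out <- character(0)
  while (!is.na(id)) {
    out <- c(out, id)
    id <- ped$mother[match(id, ped$id)]
  }
  out
}

paternal_line <- function(ped, id) {
  out <- character(0)
  while (!is.na(id)) {
    out <- c(out, id)
    id <- ped$father[match(id, ped$id)]
  }
  out
}

# score the soft constraints of a candidate pedigree against observed meta.
# Returns list(score, violations, n_constraints).
score_pedigree <- function(ped, meta, first_degree_types = NULL) {
  obs <- meta$id
  score <- 0L; total <- 0L
  violations <- character(0)
  # mt consistency along shared maternal lines
  for (i in seq_along(obs)) {
    for (j in seq_len(i - 1L)) {
      a <- obs[i]; b <- obs[j]
      mt_a <- meta$mt_haplogroup[i]; mt_b <- meta$mt_haplogroup[j]
      if (mt_a == "unknown" || mt_b == "unknown") next
      linked <- length(intersect(maternal_line(ped, a),
                                 maternal_line(ped, b))) > 0
      if (linked) {
        total <- total + 1L
        if (mt_a == mt_b) score <- score + 1L
        else violations <- c(violations,
                             sprintf("mt mismatch on maternal line: %s vs %s", a, b))
      }
    }
  }
  # Y consistency along shared paternal lines (males only)
  males <- obs[meta$genetic_sex == "XY" & meta$y_haplogroup != "unknown"]
  if (length(males) > 1) {
    for (i in seq_along(males)) {
      for (j in seq_len(i - 1L)) {
        a <- males[i]; b <- males[j]
        linked <- length(intersect(paternal_line(ped, a),
                                   paternal_line(ped, b))) > 0
        if (linked) {
          total <- total + 1L
          ya <- meta$y_haplogroup[match(a, meta$id)]
          yb <- meta$y_haplogroup[match(b, meta$id)]
          if (ya == yb) score <- score + 1L
          else violations <- c(violations,
                               sprintf("Y mismatch on paternal line: %s vs %s", a, b))
        }
      }
    }
  }
  # age: a subadult observed parent of an adult child is implausible
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (is.na(p)) next
      pi <- match(p, meta$id); ci <- match(ped$id[i], meta$id)
      if (is.na(pi) || is.na(ci)) next
      total <- total + 1L
      if (meta$age_class[pi] == "subadult" && meta$age_class[ci] == "adult") {
        violations <- c(violations,
                        sprintf("subadult %s is parent of adult %s", p, ped$id[i]))
      } else score <- score + 1L
    }
  }
  # first-degree type calls (PO vs FS) from IBD coefficients, when supplied
  if (!is.null(first_degree_types) && nrow(first_degree_types)) {
    for (r in seq_len(nrow(first_degree_types))) {
      a <- first_degree_types$id1[r]; b <- first_degree_types$id2[r]
      type <- first_degree_types$type[r]
      if (type == "undetermined") next
      total <- total + 1L
      rel <- ped_relatedness(ped, a, b)
      is_po <- abs(rel$k1 - 1) < 1e-9
      is_fs <- abs(rel$k2 - 0.25) < 1e-9 && abs(rel$k1 - 0.5) < 1e-9
      ok <- (type == "parent_offspring" && is_po) ||
        (type == "full_sibling" && is_fs)
      if (ok) score <- score + 1L
      else violations <- c(violations,
                           sprintf("%s call for %s-%s not matched", type, a, b))
    }
  }
  list(score = score, n_constraints = total, violations = violations)
}

# canonical string signature of a pedigree, latents relabelled by traversal
ped_signature <- function(ped) {
  depth <- ped_depths(ped)
  ord <- order(!ped$observed, depth, ped$id)
  latent <- ped$id[ord][!ped$observed[ord]]
  relabel <- function(x) {
    i <- match(x, latent)
    ifelse(is.na(i), x, sprintf("L%02d", i))
  }
  rows <- sprintf("%s<%s,%s", relabel(ped$id), relabel(ped$father),
                  relabel(ped$mother))
  paste(sort(rows), collapse = ";")
}

n_latent <- function(ped) sum(!ped$observed)

new_latent_id <- function(ped, sex = NA) {
  k <- sum(!ped$observed) + 1L
  sprintf("latent%02d", k)
}

add_node <- function(ped, id, sex = NA, father = NA, mother = NA,
                     observed = FALSE) {
  rbind(ped, data.frame(id = id, sex = sex, father = father, mother = mother,
                        observed = observed, mt_hg = NA_character_,
                        y_hg = NA_character_, stringsAsFactors = FALSE))
}

# set a parent of `child`, choosing the father/mother slot by parent sex
set_parent <- function(ped, child, parent) {
  ci <- match(child, ped$id)
  psex <- ped$sex[match(parent, ped$id)]
  slot <- if (!is.na(psex) && psex == "F") "mother" else
    if (!is.na(psex) && psex == "M") "father" else
      if (is.na(ped$father[ci])) "father" else "mother"
  if (!is.na(ped[[slot]][ci])) return(NULL)   # slot taken
  ped[[slot]][ci] <- parent
  ped
}

# would adding parent->child create a cycle?
creates_cycle <- function(ped, child, parent) {
  # parent must not be a descendant of child
  desc <- child
  repeat {
    kids <- ped$id[(ped$father %in% desc) | (ped$mother %in% desc)]
    new <- setdiff(kids, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  parent %in% desc
}

# substitution move: identify observed individual `x` with an existing
# latent connector of compatible sex
substitute_latent <- function(ped, x, x_sex) {
  out <- list()
  for (i in which(!ped$observed)) {
    if (!is.na(ped$sex[i]) && !is.na(x_sex) && ped$sex[i] != x_sex) next
    p <- ped
    old <- p$id[i]
    p$id[i] <- x
    p$sex[i] <- if (is.na(p$sex[i])) x_sex else p$sex[i]
    p$observed[i] <- TRUE
    p$father[p$father == old & !is.na(p$father)] <- x
    p$mother[p$mother == old & !is.na(p$mother)] <- x
    out[[length(out) + 1L]] <- p
  }
  out
}

# attachment templates: all ways to join `x` (with sex) to anchor `a` in
# `ped` realizing a given degree. Each returns a list of candidate pedigrees.
attach_candidates <- function(ped, x, x_sex, a, degree, max_latent) {
  out <- list()
  add <- function(p) if (!is.null(p) && !ped_is_inbred(p) &&
                         n_latent(p) <= max_latent) out[[length(out) + 1L]] <<- p
  ped_x <- add_node(ped, x, sex = x_sex, observed = TRUE)

  # ensure a node has a parent of a given role, creating a latent if absent;
  # returns list(ped, parent_id) or NULL
  get_parent <- function(p, node, role) {
    i <- match(node, p$id)
    cur <- p[[role]][i]
    if (!is.na(cur)) return(list(ped = p, parent = cur))
    if (n_latent(p) >= max_latent) return(NULL)
    sex <- if (role == "father") "M" else "F"
    lid <- new_latent_id(p)
    p <- add_node(p, lid, sex = sex)
    p[[role]][match(node, p$id)] <- lid
    list(ped = p, parent = lid)
  }

  if (degree == "first") {
    # x child of a (other parent implicit)
    if (!creates_cycle(ped_x, x, a)) add(set_parent(ped_x, x, a))
    # a child of x
    if (!creates_cycle(ped_x, a, x)) add(set_parent(ped_x, a, x))
    # full siblings: share both parents (latents created as needed)
    p <- ped_x
    for (role in c("father", "mother")) {
      g <- get_parent(p, a, role)
      if (is.null(g)) { p <- NULL; break }
      p <- g$ped
      p <- set_parent(p, x, g$parent)
      if (is.null(p)) break
    }
    add(p)
  } else if (degree == "second") {
    for (role in c("father", "mother")) {
      # half-siblings: share one parent
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) add(set_parent(g$ped, x, g$parent))
      # x grandparent of a: x is parent of a's `role` parent
      g <- get_parent(ped_x, a, role)
      if (!is.null(g) && !creates_cycle(g$ped, g$parent, x)) {
        add(set_parent(g$ped, g$parent, x))
      }
      # avuncular: x is full sib of a's `role` parent
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) {
        p <- g$ped; par <- g$parent; ok <- TRUE
        for (role2 in c("father", "mother")) {
          gg <- get_parent(p, par, role2)
          if (is.null(gg)) { ok <- FALSE; break }
          p <- gg$ped
          p <- set_parent(p, x, gg$parent)
          if (is.null(p)) { ok <- FALSE; break }
        }
        if (ok) add(p)
      }
    }
    # x grandchild of a: latent child of a, x child of that latent
    if (n_latent(ped_x) < max_latent && !creates_cycle(ped_x, x, a)) {
      lid <- new_latent_id(ped_x)
      for (lsex in c("M", "F")) {
        p <- add_node(ped_x, lid, sex = lsex)
        p <- set_parent(p, lid, a)
        if (!is.null(p)) add(set_parent(p, x, lid))
      }
    }
    # nephew/niece: x child of a full sib of a
    p0 <- ped_x; ok <- TRUE; parents <- character(0)
    for (role in c("father", "mother")) {
      g <- get_parent(p0, a, role)
      if (is.null(g)) { ok <- FALSE; break }
      p0 <- g$ped; parents <- c(parents, g$parent)
    }
    if (ok && n_latent(p0) < max_latent) {
      sid <- new_latent_id(p0)
      for (ssex in c("M", "F")) {
        p <- add_node(p0, sid, sex = ssex)
        for (par in parents) p <- set_parent(p, sid, par)
        if (!is.null(p)) add(set_parent(p, x, sid))
      }
    }
  } else if (degree == "third") {
    for (role in c("father", "mother")) {
      # half-avuncular: x half-sib of a's parent
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) {
        for (role2 in c("father", "mother")) {
          gg <- get_parent(g$ped, g$parent, role2)
          if (!is.null(gg)) add(set_parent(gg$ped, x, gg$parent))
        }
      }
      # great-grandparent: x parent of a grandparent of a
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) {
        for (role2 in c("father", "mother")) {
          gg <- get_parent(g$ped, g$parent, role2)
          if (!is.null(gg) && !creates_cycle(gg$ped, gg$parent, x)) {
            add(set_parent(gg$ped, gg$parent, x))
          }
        }
      }
      # first cousin: x child of a full sib of a's parent
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) {
        p0 <- g$ped; par <- g$parent; ok <- TRUE; gps <- character(0)
        for (role2 in c("father", "mother")) {
          gg <- get_parent(p0, par, role2)
          if (is.null(gg)) { ok <- FALSE; break }
          p0 <- gg$ped; gps <- c(gps, gg$parent)
        }
        if (ok && n_latent(p0) < max_latent) {
          sid <- new_latent_id(p0)
          for (ssex in c("M", "F")) {
            p <- add_node(p0, sid, sex = ssex)
            for (gp in gps) p <- set_parent(p, sid, gp)
            if (!is.null(p)) add(set_parent(p, x, sid))
          }
        }
      }
      # half-nephew: x child of a half-sib of a
      g <- get_parent(ped_x, a, role)
      if (!is.null(g) && n_latent(g$ped) < max_latent) {
        sid <- new_latent_id(g$ped)
        for (ssex in c("M", "F")) {
          p <- add_node(g$ped, sid, sex = ssex)
          p <- set_parent(p, sid, g$parent)
          if (!is.null(p)) add(set_parent(p, x, sid))
        }
      }
      # grand-avuncular: x full sib of a grandparent of a
      g <- get_parent(ped_x, a, role)
      if (!is.null(g)) {
        for (role2 in c("father", "mother")) {
          gg <- get_parent(g$ped, g$parent, role2)
          if (is.null(gg)) next
          p0 <- gg$ped; gpar <- gg$parent; ok <- TRUE
          p <- p0
          for (role3 in c("father", "mother")) {
            g3 <- get_parent(p, gpar, role3)
            if (is.null(g3)) { ok <- FALSE; break }
            p <- g3$ped
            p <- set_parent(p, x, g3$parent)
            if (is.null(p)) { ok <- FALSE; break }
          }
          if (ok) add(p)
        }
      }
    }
    # great-grandchild: chain of two latents down from a
    if (n_latent(ped_x) + 2L <= max_latent && !creates_cycle(ped_x, x, a)) {
      l1 <- sprintf("latent%02d", n_latent(ped_x) + 1L)
      l2 <- sprintf("latent%02d", n_latent(ped_x) + 2L)
      p <- add_node(ped_x, l1, sex = "M")
      p <- set_parent(p, l1, a)
      if (!is.null(p)) {
        p <- add_node(p, l2, sex = "M")
        p <- set_parent(p, l2, l1)
        if (!is.null(p)) add(set_parent(p, x, l2))
      }
    }
    # grand-nephew: x grandchild of a full sib of a
    p0 <- ped_x; ok <- TRUE; parents <- character(0)
    for (role in c("father", "mother")) {
      g <- get_parent(p0, a, role)
      if (is.null(g)) { ok <- FALSE; break }
      p0 <- g$ped; parents <- c(parents, g$parent)
    }
    if (ok && n_latent(p0) + 2L <= max_latent) {
      sid <- sprintf("latent%02d", n_latent(p0) + 1L)
      cid <- sprintf("latent%02d", n_latent(p0) + 2L)
      p <- add_node(p0, sid, sex = "M")
      for (par in parents) p <- set_parent(p, sid, par)
      if (!is.null(p)) {
        p <- add_node(p, cid, sex = "M")
        p <- set_parent(p, cid, sid)
        if (!is.null(p)) add(set_parent(p, x, cid))
      }
    }
  }
  out
}

#' Enumerate pedigrees consistent with pairwise degree calls
#'
#' Performs a bounded exhaustive search over pedigrees whose expected degree
#' between every pair of observed individuals reproduces the observed degree
#' matrix. Individuals are inserted one at a time; each insertion branches
#' over relationship templates (parent/child/full-sibling for first degree;
#' half-sibling, grandparent/grandchild, avuncular for second;
#' half-avuncular, first-cousin, great-grandparent and related chains for
#' third), creating at most `max_latent` latent connectors. Surviving
#' pedigrees are scored on soft constraints -- mitochondrial identity along
#' shared maternal lines, Y identity along shared paternal lines, adult
#' parents for adult offspring, and (when supplied) parent-offspring versus
#' full-sibling calls from IBD coefficients -- and returned ranked, never
#' silently collapsed to one.
#'
#' @param meta an [individual_meta()] for the observed individuals.
#' @param degrees data frame with columns `id1`, `id2`, `degree` covering
#'   every observed pair (degrees beyond third are `"unrelated"`).
#' @param first_degree_types optional data frame `id1`, `id2`, `type`
#'   (`"parent_offspring"`, `"full_sibling"`, `"undetermined"`).
#' @param max_latent maximum number of explicit latent connectors.
#' @param max_generations maximum number of generation levels spanned by the
#'   *observed* individuals (latent ancestors above the oldest observed
#'   generation are not counted against this bound).
#' @return list of class `pedigree_set`: `reports` (a list, ranked by score,
#'   each with `pedigree`, `score`, `n_constraints`, `violations`),
#'   `co_maximal` (indices of reports attaining the top score), `near_miss`
#'   (`TRUE` when no pedigree matched the degree matrix exactly and
#'   third-degree/unrelated calls were treated as interchangeable -- the
#'   expected mismatch rate of a fourth-degree pair lies exactly on that
#'   boundary -- with deviations listed under `violations`) and
#'   `n_searched`.
#' @export
enumerate_pedigrees <- function(meta, degrees, first_degree_types = NULL,
                                max_latent = 4, max_generations = 3) {
  obs <- meta$id
  if (length(obs) < 2) stop("enumerate_pedigrees: need >= 2 individuals",
                            call. = FALSE)
  deg <- function(a, b) {
    hit <- (degrees$id1 == a & degrees$id2 == b) |
      (degrees$id1 == b & degrees$id2 == a)
    if (!any(hit)) stop(sprintf("degree call missing for pair %s-%s", a, b),
                        call. = FALSE)
    degrees$degree[which(hit)[1]]
  }
  sex_of <- function(id) {
    s <- meta$genetic_sex[match(id, meta$id)]
    if (s == "XY") "M" else if (s == "XX") "F" else NA_character_
  }
  # insertion order: most-connected first
  related_count <- vapply(obs, function(a)
    sum(vapply(setdiff(obs, a), function(b) deg(a, b) != "unrelated", TRUE)),
    integer(1))
  ord <- obs[order(-related_count, obs)]

  # in near-miss (relaxed) mode, third-degree and unrelated calls are
  # interchangeable during the search -- the expected mismatch rate of a
  # fourth-degree pair sits exactly on that classification boundary -- and
  # deviations are reported as violated constraints instead
  deg_ok <- function(expected, observed, relaxed) {
    expected == observed ||
      (relaxed && all(c(expected, observed) %in% c("third", "unrelated")))
  }

  n_searched <- 0L
  search <- function(relaxed) {
    states <- list(pedigree(ord[1], sex = sex_of(ord[1])))
    for (k in seq_along(ord)[-1]) {
      x <- ord[k]
      nxt <- list()
      seen <- character(0)
      for (st in states) {
        placed <- intersect(ord[seq_len(k - 1L)], st$id)
        degs_x <- vapply(placed, function(b) deg(x, b), character(1))
        anchors <- placed[degs_x != "unrelated"]
        cands <- if (!length(anchors)) {
          # unrelated to everything placed so far: isolated founder
          list(add_node(st, x, sex = sex_of(x), observed = TRUE))
        } else {
          # anchor on every placed relative of the closest degree, and also
          # consider identifying x with an existing latent connector
          rank <- match(degs_x, c("identical", "first", "second", "third"))
          close <- placed[which(rank == min(rank, na.rm = TRUE))]
          cc <- substitute_latent(st, x, sex_of(x))
          for (a in close) {
            cc <- c(cc, attach_candidates(st, x, sex_of(x), a,
                                          degs_x[match(a, placed)], max_latent))
          }
          cc
        }
        for (cand in cands) {
          n_searched <<- n_searched + 1L
          # verify x against every placed observed individual
          depth <- tryCatch(ped_depths(cand), error = function(e) NULL)
          if (is.null(depth)) next
          if (ped_generation_span(cand) > max_generations) next
          memo <- new.env(parent = emptyenv())
          ok <- TRUE
          for (b in placed) {
            kap <- ped_kinship(cand, x, b, depth, memo)
            if (!deg_ok(degree_from_kappa(kap), deg(x, b), relaxed)) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
          sig <- ped_signature(cand)
          if (sig %in% seen) next
          seen <- c(seen, sig)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
      states <- nxt
      if (!length(states)) break
    }
    states
  }

  finalize <- function(states, relaxed) {
    reports <- list()
    for (st in states) {
      depth <- ped_depths(st)
      memo <- new.env(parent = emptyenv())
      ok <- TRUE
      deg_viol <- character(0)
      n_deg <- 0L; n_deg_ok <- 0L
      for (i in seq_along(obs)) {
        for (j in seq_len(i - 1L)) {
          kap <- ped_kinship(st, obs[i], obs[j], depth, memo)
          expd <- degree_from_kappa(kap)
          obsd <- deg(obs[i], obs[j])
          if (!deg_ok(expd, obsd, relaxed)) { ok <- FALSE; break }
          n_deg <- n_deg + 1L
          if (expd == obsd) n_deg_ok <- n_deg_ok + 1L
          else deg_viol <- c(deg_viol,
                             sprintf("degree near-miss %s-%s: called %s, pedigree implies %s",
                                     obs[i], obs[j], obsd, expd))
        }
        if (!ok) break
      }
      if (!ok) next
      sc <- score_pedigree(st, meta, first_degree_types)
      if (relaxed) {
        sc$score <- sc$score + n_deg_ok
        sc$n_constraints <- sc$n_constraints + n_deg
        sc$violations <- c(deg_viol, sc$violations)
      }
      reports[[length(reports) + 1L]] <- c(list(pedigree = st), sc)
    }
    reports
  }

  relaxed <- FALSE
  reports <- finalize(search(FALSE), FALSE)
  if (!length(reports)) {
    relaxed <- TRUE
    reports <- finalize(search(TRUE), TRUE)
  }
  if (length(reports)) {
    scores <- vapply(reports, `[[`, integer(1), "score")
    ord_r <- order(-scores)
    reports <- reports[ord_r]
    scores <- scores[ord_r]
    co_max <- which(scores == scores[1])
  } else co_max <- integer(0)
  structure(list(reports = reports, co_maximal = co_max,
                 near_miss = relaxed, n_searched = n_searched),
            class = "pedigree_set")
}

#' @export
print.pedigree_set <- function(x, ...) {
  cat(sprintf("<pedigree_set> %d consistent pedigree(s), %d co-maximal (searched %d)\n",
              length(x$reports), length(x$co_maximal), x$n_searched))
  for (i in seq_along(x$reports)) {
    r <- x$reports[[i]]
    cat(sprintf("-- rank %d: score %d/%d\n", i, r$score, r$n_constraints))
    cat(paste0("   ", render_pedigree(r$pedigree)$text, collapse = "\n"), "\n")
  }
  invisible(x)
}
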