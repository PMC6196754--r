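# Parentage assignment by opposing-homozygote exclusion and full-sib family
# construction.

#' Count opposing homozygotes between two coded genotype vectors
#'
#' Markers where both individuals are called and one is hom-ref while the
#' other is hom-alt; impossible for a true parent-offspring pair without
#' genotyping error, hence the basis of exclusion parentage.
#'
#' @param offspring,candidate Equal-length integer vectors coded
#'   \{0, 1, 2, -1\}.
#' @return Named integer-ish list: `conflicts` and `informative` (markers
#'   where both are called).
#' @examples
#' count_opposing_homozygotes(c(0, 2, 1, 0), c(2, 0, 1, 0))$conflicts  # 2
#' @export
count_opposing_homozygotes <- function(offspring, candidate) {
  assert_that(length(offspring) == length(candidate),
              "genotype vectors must have equal length")
  both <- offspring >= 0L & candidate >= 0L
  conf <- sum((offspring == 0L & candidate == 2L) |
                (offspring == 2L & candidate == 0L))
  list(conflicts = as.integer(conf), informative = as.integer(sum(both)))
}

# All-pairs opposing-homozygote counts via matrix products.
opposing_matrix <- function(off, cand) {
  o0 <- (off == 0L) * 1; o2 <- (off == 2L) * 1
  c0 <- (cand == 0L) * 1; c2 <- (cand == 2L) * 1
  o0 %*% t(c2) + o2 %*% t(c0)
}

#' Assign parents by opposing-homozygote exclusion
#'
#' Per offspring, every candidate with a conflict count at or below the
#' threshold is accepted. With candidate sexes known, the assigned pair is
#' the lowest-conflict accepted male and female. Without sexes, the two
#' lowest-conflict accepted candidates are paired when the resulting trio is
#' Mendelian-consistent at a fraction of markers of at least
#' `1 - trio_tolerance`. Offspring with fewer than two accepted candidates
#' are left unresolved (a legal outcome).
#'
#' @param gm A [genotype_matrix()] holding offspring and candidates.
#' @param offspring Character vector of offspring sample ids.
#' @param candidates Character vector of candidate-parent sample ids.
#' @param max_conflicts Absolute conflict threshold; overrides
#'   `max_conflict_frac` when given.
#' @param max_conflict_frac Threshold as a fraction of the pair's informative
#'   (both-called) markers (default 0.0024, the published 100-of-43,014
#'   convention).
#' @param sexes Optional tibble `id`, `sex` for the candidates (12/M = male,
#'   11/F = female).
#' @param trio_tolerance Maximum tolerated trio Mendelian-error fraction when
#'   pairing without sexes (default 0.01).
#' @return An object of class `pedigree_assignment`: tibble `assignments`
#'   (`id`, `sire`, `dam`, `sire_conflicts`, `dam_conflicts`, `n_accepted`,
#'   `resolved`, `ambiguous`) plus the full `accepted` long tibble.
#' @export
assign_parents <- function(gm, offspring, candidates,
                           max_conflicts = NULL, max_conflict_frac = 0.0024,
                           sexes = NULL, trio_tolerance = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_that(all(offspring %in% gm$samples) && all(candidates %in% gm$samples),
              "offspring/candidates must be rows of the genotype matrix")
  off <- gm$codes[offspring, , drop = FALSE]
  cand <- gm$codes[candidates, , drop = FALSE]
  conf <- opposing_matrix(off, cand)
  called_off <- (off >= 0L) * 1
  called_cand <- (cand >= 0L) * 1
  informative <- called_off %*% t(called_cand)
  thr <- if (!is.null(max_conflicts)) {
    matrix(max_conflicts, nrow(conf), ncol(conf))
  } else {
    max_conflict_frac * informative
  }
  acc <- conf <= thr

  sex_of <- rep(NA_character_, length(candidates))
  if (!is.null(sexes)) {
    sex_of <- normalize_sex(sexes$sex[match(candidates, sexes$id)])
  }

  pick <- function(i) {
    ok <- which(acc[i, ])
    n_acc <- length(ok)
    if (n_acc < 2) {
      return(tibble(id = offspring[i], sire = NA_character_, dam = NA_character_,
                    sire_conflicts = NA_integer_, dam_conflicts = NA_integer_,
                    n_accepted = n_acc, resolved = FALSE, ambiguous = FALSE))
    }
    ord <- ok[order(conf[i, ok])]
    if (!is.null(sexes)) {
      males <- ord[sex_of[ord] %in% "M"]
      females <- ord[sex_of[ord] %in% "F"]
      if (!length(males) || !length(females)) {
        return(tibble(id = offspring[i], sire = NA_character_, dam = NA_character_,
                      sire_conflicts = NA_integer_, dam_conflicts = NA_integer_,
                      n_accepted = n_acc, resolved = FALSE,
                      ambiguous = n_acc > 2))
      }
      s <- males[1]; d <- females[1]
    } else {
      s <- d <- NA
      # two lowest-conflict candidates whose trio passes the Mendelian check
      for (a in seq_len(min(4, length(ord) - 1))) {
        for (b in seq(a + 1, min(a + 4, length(ord)))) {
          err <- trio_error_rate(off[i, ], cand[ord[a], ], cand[ord[b], ])
          if (!is.na(err) && err <= trio_tolerance) { s <- ord[a]; d <- ord[b]; break }
        }
        if (!is.na(s)) break
      }
      if (is.na(s)) {
        return(tibble(id = offspring[i], sire = NA_character_, dam = NA_character_,
                      sire_conflicts = NA_integer_, dam_conflicts = NA_integer_,
                      n_accepted = n_acc, resolved = FALSE,
                      ambiguous = n_acc > 2))
      }
    }
    tibble(id = offspring[i],
           sire = candidates[s], dam = candidates[d],
           sire_conflicts = as.integer(conf[i, s]),
           dam_conflicts = as.integer(conf[i, d]),
           n_accepted = n_acc, resolved = TRUE, ambiguous = n_acc > 2)
  }
  assignments <- purrr::map_dfr(seq_along(offspring), pick)
  accepted <- tibble(
    id = rep(offspring, each = length(candidates)),
    candidate = rep(candidates, length(offspring)),
    conflicts = as.integer(t(conf)),
    informative = as.integer(t(informative)),
    accepted = as.logical(t(acc)))
  structure(list(assignments = assignments,
                 accepted = accepted[accepted$accepted, , drop = FALSE],
                 conflicts = conf),
            class = "pedigree_assignment")
}

# Fraction of called trio markers whose offspring genotype is impossible
# given the two candidate parents.
trio_error_rate <- function(off, p1, p2) {
  ok <- off >= 0L & p1 >= 0L & p2 >= 0L
  if (!any(ok)) return(NA_real_)
  o <- off[ok]; a <- p1[ok]; b <- p2[ok]
  lo <- pmax(0L, (a > 1) + (b > 1))        # minimum alt dosage transmissible
  hi <- (a > 0L) + (b > 0L)                # maximum alt dosage transmissible
  mean(o < lo | o > hi)
}

#' @export
print.pedigree_assignment <- function(x, ...) {
  cat("<pedigree_assignment> ", nrow(x$assignments), " offspring, ",
      sum(x$assignments$resolved), " resolved\n", sep = "")
  invisible(x)
}

#' Tidy a pedigree assignment
#' @param x A `pedigree_assignment`.
#' @param ... Unused.
#' @return The per-offspring assignment tibble.
#' @method tidy pedigree_assignment
#' @export
tidy.pedigree_assignment <- function(x, ...) x$assignments

#' Build full-sib families from parentage assignments
#'
#' Groups resolved offspring by (sire, dam). Families below the minimum size
#' are dropped from the mapping set but reported.
#'
#' @param assignments A `pedigree_assignment` or its tidied tibble (`id`,
#'   `sire`, `dam`).
#' @param min_size Minimum family size retained for mapping (default 8).
#' @return An object of class `family_table`: `families` (kept), `dropped`,
#'   and `stats` (n families, mean and sd of offspring per kept family).
#' @examples
#' asg <- tibble::tibble(id = paste0("o", 1:9),
#'                       sire = "s1", dam = "d1")
#' build_families(asg, min_size = 8)
#' @export
build_families <- function(assignments, min_size = 8) {
  tbl <- if (inherits(assignments, "pedigree_assignment")) {
    assignments$assignments
  } else as_tibble(assignments)
  tbl <- tbl[!is.na(tbl$sire) & !is.na(tbl$dam), , drop = FALSE]
  fam <- tbl |>
    dplyr::group_by(.data$sire, .data$dam) |>
    dplyr::summarise(offspring = list(.data$id), size = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size))
  keep <- fam$size >= min_size
  kept <- fam[keep, , drop = FALSE]
  stats <- tibble(
    n_families = nrow(kept),
    n_offspring = sum(kept$size),
    mean_size = if (nrow(kept)) round_half_up(mean(kept$size), 2) else NA_real_,
    sd_size = if (nrow(kept) > 1) round_half_up(stats::sd(kept$size), 2) else NA_real_,
    n_dropped = sum(!keep))
  structure(list(families = kept, dropped = fam[!keep, , drop = FALSE],
                 stats = stats, min_size = min_size),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  s <- x$stats
  cat("<family_table> ", s$n_families, " families, ", s$n_offspring,
      " offspring (mean ", s$mean_size,
      if (!is.na(s$sd_size)) paste0(" ± ", s$sd_size), "); ",
      s$n_dropped, " dropped below size ", x$min_size, "\n", sep = "")
  invisible(x)
}

#' Tidy a family table
#' @param x A `family_table`.
#' @param ... Unused.
#' @return Tibble of kept families (`sire`, `dam`, `size`).
#' @method tidy family_table
#' @export
tidy.family_table <- function(x, ...) {
  dplyr::select(x$families, "sire", "dam", "size")
}

#' One-line family statistics
#' @param x A `family_table`.
#' @param ... Unused.
#' @return The statistics tibble (n families, mean/sd size, dropped).
#' @method glance family_table
#' @export
glance.family_table <- function(x, ...) x$stats
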