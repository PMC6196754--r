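# Fixed physical-order sex-specific linkage-map estimation: transmission
# resolution, min-recombination phasing, crossover counting between
# consecutive resolved markers, Kosambi/Haldane distances, recombination
# deserts and XY sex-locus mapping.

#' Mapping functions
#'
#' Kosambi: `d(cM) = 25 ln((1 + 2r) / (1 - 2r))`, partially accounting for
#' crossover interference; Haldane: `d(cM) = -50 ln(1 - 2r)`, no
#' interference. The inverses convert additive distances back to
#' recombination fractions.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM.
#' @return Numeric vector.
#' @examples
#' kosambi_cm(0.25)        # 25 * log(3) ~ 27.465
#' kosambi_inv(kosambi_cm(0.1))
#' @export
kosambi_cm <- function(r) {
  assert_that(all(r >= 0 & r < 0.5), "r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_inv <- function(d) tanh(d / 50) / 2

#' @rdname kosambi_cm
#' @export
haldane_cm <- function(r) {
  assert_that(all(r >= 0 & r < 0.5), "r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi_cm
#' @export
haldane_inv <- function(d) (1 - exp(-d / 50)) / 2

mapping_funs <- list(kosambi = kosambi_cm, haldane = haldane_cm)

#' Resolve allele transmissions within one full-sib trio set
#'
#' At markers where a parent is heterozygous, the transmitted allele (0 =
#' ref, 1 = alt) is resolved when the offspring genotype together with the
#' other parent's genotype determines it uniquely; both-parents-het with a
#' het offspring stays unknown. Mendelian-inconsistent trio genotypes leave
#' the indicator unknown and flag the marker.
#'
#' @param gm A [genotype_matrix()].
#' @param sire,dam Sample ids of the two parents.
#' @param offspring Character vector of offspring sample ids.
#' @return List with `sire` and `dam` indicator matrices (offspring x
#'   markers; 0/1/NA), and `mendel_flagged` marker ids.
#' @export
resolve_transmissions <- function(gm, sire, dam, offspring) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_that(all(c(sire, dam, offspring) %in% gm$samples),
              "trio samples must be rows of the genotype matrix")
  O <- gm$codes[offspring, , drop = FALSE]
  s <- gm$codes[sire, ]; d <- gm$codes[dam, ]
  ts <- transmission_matrix(O, s, d)
  td <- transmission_matrix(O, d, s)
  flagged <- gm$markers$marker[colSums(ts$mendel | td$mendel) > 0]
  list(sire = ts$ind, dam = td$ind, mendel_flagged = flagged)
}

# Indicator of which allele the focal parent transmitted, given the other
# parent's genotype. O: offspring x markers; focal/other: genotype vectors.
transmission_matrix <- function(O, focal, other) {
  n <- nrow(O); m <- ncol(O)
  FO <- matrix(focal, n, m, byrow = TRUE)
  Q <- matrix(other, n, m, byrow = TRUE)
  t <- matrix(NA_integer_, n, m, dimnames = dimnames(O))
  t[Q == 0L & O == 0L] <- 0L
  t[Q == 0L & O == 1L] <- 1L
  t[Q == 2L & O == 1L] <- 0L
  t[Q == 2L & O == 2L] <- 1L
  t[Q == 1L & O == 0L] <- 0L
  t[Q == 1L & O == 2L] <- 1L
  mendel <- (Q == 0L & O == 2L) | (Q == 2L & O == 0L) |
    (FO == 0L & O == 2L) | (FO == 2L & O == 0L) |
    (FO == 0L & Q == 0L & O > 0L) | (FO == 2L & Q == 2L & O < 2L & O >= 0L)
  t[FO != 1L] <- NA_integer_   # only heterozygous-parent markers informative
  t[mendel] <- NA_integer_
  list(ind = t, mendel = mendel)
}

#' Minimum-recombination phasing of one parent on one linkage group
#'
#' Chooses a phase bit per informative marker minimising the total crossover
#' count summed over the parent's offspring. The 2-state phase chain
#' decouples per interval: between adjacent informative markers the cost is
#' the number of offspring whose transmission indicators flip (`d`) under
#' equal phase, or `n - d` under opposite phase, so the optimum takes
#' `min(d, n - d)` per interval with ties broken toward no phase flip. The
#' result equals exhaustive minimisation over all `2^M` phase vectors.
#'
#' @param A Indicator matrix (offspring x informative markers; 0/1/NA) for
#'   one parent on one linkage group, markers in physical order.
#' @return List: `hap` (haplotype-of-origin matrix, 0/1/NA), `phase` (phase
#'   bit per marker), `crossovers` (total minimal crossover count),
#'   `interval_cost` (per-interval crossover counts), and `broken` (logical
#'   per interval: the relative phase across it is unidentifiable or too
#'   weakly supported — fewer than `min_link_n` offspring resolved at both
#'   flanks, or an exact cost tie — so haplotype comparisons across such
#'   links are not trustworthy).
#' @param min_link_n Minimum number of both-resolved offspring for a phase
#'   link to count as identifiable (default 3).
#' @export
phase_parent <- function(A, min_link_n = 3) {
  A <- as.matrix(A)
  m <- ncol(A)
  if (m == 0) {
    return(list(hap = A, phase = integer(0), crossovers = 0L,
                interval_cost = integer(0), broken = logical(0)))
  }
  if (m == 1) {
    return(list(hap = A, phase = 0L, crossovers = 0L,
                interval_cost = integer(0), broken = logical(0)))
  }
  left <- A[, -m, drop = FALSE]; right <- A[, -1, drop = FALSE]
  both <- !is.na(left) & !is.na(right)
  d <- colSums(left != right & both, na.rm = TRUE)
  n <- colSums(both)
  flip <- (n - d) < d
  cost <- pmin(d, n - d)
  phase <- as.integer(cumsum(c(0L, flip)) %% 2L)
  hap <- abs(sweep(A, 2, phase))
  list(hap = hap, phase = phase, crossovers = as.integer(sum(cost)),
       interval_cost = as.integer(cost),
       broken = n < min_link_n | d * 2L == n)
}

# Mask short haplotype flips as genotyping errors. Within each offspring's
# resolved sequence, maximal blocks of consecutive short runs (each of
# <= run_max markers) bounded by agreeing runs of >= w markers — or by the
# sequence edge — are set unknown. A genuine double crossover confined to
# run_max adjacent markers has probability ~r^2 per meiosis, vanishingly
# rarer than a genotyping error; a genuine crossover flanked by an error
# block still yields exactly one flip across the masked gap.
mask_isolated_flips <- function(H, w = 2, run_max = 2) {
  for (i in seq_len(nrow(H))) {
    idx <- which(!is.na(H[i, ]))
    if (length(idx) < 2) next
    r <- rle(H[i, idx])
    L <- r$lengths
    k <- length(L)
    if (k < 2 || all(L <= run_max)) next
    short <- L <= run_max
    b <- rle(short)
    bends <- cumsum(b$lengths); bstarts <- bends - b$lengths + 1
    ends <- cumsum(L); starts <- ends - L + 1
    for (j in which(b$values)) {
      left_ok <- bstarts[j] == 1 || L[bstarts[j] - 1] >= w
      right_ok <- bends[j] == k || L[bends[j] + 1] >= w
      if (left_ok && right_ok) {
        H[i, idx[seq(starts[bstarts[j]], ends[bends[j]])]] <- NA_integer_
      }
    }
  }
  H
}

# Stack transmission indicators for one parent across all of its families.
resolve_for_parent <- function(gm, ped, parent, role) {
  other_role <- if (role == "sire") "dam" else "sire"
  rows <- ped[ped[[role]] %in% parent, , drop = FALSE]
  off_ids <- rows$id
  others <- rows[[other_role]]
  m <- ncol(gm$codes)
  T <- matrix(NA_integer_, length(off_ids), m,
              dimnames = list(off_ids, colnames(gm$codes)))
  pg <- gm$codes[parent, ]
  for (og in unique(others)) {
    sel <- which(others == og)
    O <- gm$codes[off_ids[sel], , drop = FALSE]
    T[sel, ] <- transmission_matrix(O, pg, gm$codes[og, ])$ind
  }
  list(ind = T, offspring = off_ids, het = which(pg == 1L))
}

#' Estimate sex-specific linkage maps under a fixed physical order
#'
#' For every parent and linkage group, transmission indicators are resolved,
#' phased by minimum recombination, and (optionally) cleaned of isolated
#' single-marker flips. Crossovers are then counted between consecutive
#' resolved markers of each meiosis; each crossover is assigned once to its
#' bracketing span and distributed over the spanned physical intervals in
#' proportion to their length. Per-interval recombination fractions pool the
#' meioses of each parental sex (`r = events / covering meioses`, capped at
#' `0.5 - 1e-6`), interval distances come from the chosen mapping function,
#' and cumulative sums give the female, male and (pooled-meiosis)
#' sex-averaged cM tracks. Intervals never covered by an informative meiosis
#' get a zero increment and a gap flag.
#'
#' @param gm A [genotype_matrix()] holding parents and offspring.
#' @param pedigree Tibble `id`, `sire`, `dam` (offspring rows; parents must
#'   be genotyped). Extra rows with missing sire/dam are ignored.
#' @param mapping_fun `"kosambi"` (default) or `"haldane"`.
#' @param mask_flips Mask isolated single-marker double-crossovers as
#'   genotyping errors (default TRUE).
#' @param mask_w Required flanking agreement run length for masking
#'   (default 2).
#' @return An object of class `genetic_map`: `positions` tibble (`lg`,
#'   `marker`, `bp`, `cm_female`, `cm_male`, `cm_sexavg`), `intervals`
#'   tibble with per-sex `r`, coverage `n` and gap flags, and metadata.
#' @export
estimate_map <- function(gm, pedigree, mapping_fun = c("kosambi", "haldane"),
                         mask_flips = TRUE, mask_w = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mapping_fun <- match.arg(mapping_fun)
  mf <- mapping_funs[[mapping_fun]]
  ped <- as_tibble(pedigree)
  ped <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
               ped$id %in% gm$samples & ped$sire %in% gm$samples &
               ped$dam %in% gm$samples, , drop = FALSE]
  assert_that(nrow(ped) > 0, "no usable trios in pedigree", "onilmap_precondition")

  mk <- gm$markers
  lgs <- unique(mk$chrom)
  acc <- lapply(lgs, function(lg) {
    m <- sum(mk$chrom == lg)
    list(dn_f = numeric(m), de_f = numeric(m),
         dn_m = numeric(m), de_m = numeric(m))
  })
  names(acc) <- lgs
  lg_idx <- split(seq_len(nrow(mk)), mk$chrom)[lgs]

  for (role in c("sire", "dam")) {
    parents <- unique(ped[[role]])
    for (p in parents) {
      res <- resolve_for_parent(gm, ped, p, role)
      if (!length(res$offspring)) next
      for (lg in lgs) {
        gidx <- lg_idx[[lg]]
        inf_local <- which(gidx %in% res$het)
        if (length(inf_local) < 2) next
        A <- res$ind[, gidx[inf_local], drop = FALSE]
        ph <- phase_parent(A)
        H <- ph$hap
        if (mask_flips) H <- mask_isolated_flips(H, mask_w)
        # spans crossing a phase break carry no usable signal
        cb <- c(0, cumsum(ph$broken))
        pos <- mk$pos[gidx]
        a <- acc[[lg]]
        dn <- if (role == "sire") "dn_m" else "dn_f"
        de <- if (role == "sire") "de_m" else "de_f"
        for (i in seq_len(nrow(H))) {
          hk <- which(!is.na(H[i, ]))
          if (length(hk) < 2) next
          v <- H[i, hk]
          ok <- cb[hk[-1]] - cb[hk[-length(hk)]] == 0
          if (!any(ok)) next
          from <- inf_local[hk[-length(hk)][ok]]
          to <- inf_local[hk[-1][ok]]
          a[[dn]][from] <- a[[dn]][from] + 1
          a[[dn]][to] <- a[[dn]][to] - 1
          fl <- which(v[-length(v)][ok] != v[-1][ok])
          if (length(fl)) {
            wgt <- 1 / (pos[to[fl]] - pos[from[fl]])
            a[[de]][from[fl]] <- a[[de]][from[fl]] + wgt
            a[[de]][to[fl]] <- a[[de]][to[fl]] - wgt
          }
        }
        acc[[lg]] <- a
      }
    }
  }

  positions <- NULL
  intervals <- NULL
  for (lg in lgs) {
    gidx <- lg_idx[[lg]]
    m <- length(gidx)
    pos <- mk$pos[gidx]
    a <- acc[[lg]]
    if (m < 2) {
      positions <- dplyr::bind_rows(positions, tibble(
        lg = lg, marker = mk$marker[gidx], bp = pos,
        cm_female = 0, cm_male = 0, cm_sexavg = 0))
      next
    }
    len <- diff(pos)
    tr <- function(dn, de) {
      n <- cumsum(dn)[-m]
      e <- cumsum(de)[-m] * len
      r <- ifelse(n > 0, pmin(pmax(e / n, 0), 0.5 - 1e-6), 0)
      list(r = r, n = n, gap = n == 0)
    }
    f <- tr(a$dn_f, a$de_f)
    mm <- tr(a$dn_m, a$de_m)
    sa <- tr(a$dn_f + a$dn_m, a$de_f + a$de_m)
    positions <- dplyr::bind_rows(positions, tibble(
      lg = lg, marker = mk$marker[gidx], bp = pos,
      cm_female = c(0, cumsum(mf(f$r))),
      cm_male = c(0, cumsum(mf(mm$r))),
      cm_sexavg = c(0, cumsum(mf(sa$r)))))
    intervals <- dplyr::bind_rows(intervals, tibble(
      lg = lg,
      left = mk$marker[gidx[-m]], right = mk$marker[gidx[-1]],
      left_bp = pos[-m], right_bp = pos[-1],
      r_female = f$r, n_female = f$n, gap_female = f$gap,
      r_male = mm$r, n_male = mm$n, gap_male = mm$gap,
      r_sexavg = sa$r, n_sexavg = sa$n, gap_sexavg = sa$gap))
  }
  structure(list(positions = positions, intervals = intervals,
                 mapping_fun = mapping_fun, mask_flips = mask_flips,
                 n_meioses = 2L * nrow(ped)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  tot <- x$positions |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(f = max(.data$cm_female), m = max(.data$cm_male),
                     sa = max(.data$cm_sexavg), .groups = "drop")
  cat("<genetic_map> ", nrow(x$positions), " markers on ",
      nrow(tot), " LGs (", x$mapping_fun, ")\n", sep = "")
  cat("  total cM  female ", round(sum(tot$f), 1), " | male ",
      round(sum(tot$m), 1), " | sex-avg ", round(sum(tot$sa), 1), "\n", sep = "")
  invisible(x)
}

#' Tidy a genetic map
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return The per-marker position tibble (`lg`, `marker`, `bp`,
#'   `cm_female`, `cm_male`, `cm_sexavg`).
#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) x$positions

#' One-line totals of a genetic map
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return One-row tibble: marker count, total lengths per track, F:M
#'   factor.
#' @method glance genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  per <- x$positions |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(f = max(.data$cm_female), m = max(.data$cm_male),
                     sa = max(.data$cm_sexavg), .groups = "drop")
  tibble(n_markers = nrow(x$positions), n_lgs = nrow(per),
         female_cm = sum(per$f), male_cm = sum(per$m),
         sexavg_cm = sum(per$sa),
         fm_factor = round_half_up(sum(per$f) / sum(per$m), 2))
}

#' Detect recombination deserts
#'
#' Maximal runs of consecutive intervals whose recombination rate (cM/Mb) is
#' at or below `max_rate`, spanning at least `min_span` bp. Runs touching a
#' linkage-group end are flagged terminal.
#'
#' @param map A `genetic_map`.
#' @param min_span Minimum physical span, bp (default 1e6).
#' @param max_rate Maximum rate inside a desert, cM/Mb (default 0.05).
#' @param track Which cM track to use: `"sexavg"` (default), `"female"`,
#'   `"male"`.
#' @param bridge_cm High-rate stretches accumulating no more than this much
#'   genetic length are bridged into the surrounding desert (smooths
#'   single-interval blips from residual genotyping error; default
#'   0.25 cM).
#' @return Tibble `lg`, `start_bp`, `end_bp`, `span_bp`, `terminal`.
#' @export
detect_deserts <- function(map, min_span = 1e6, max_rate = 0.05,
                           track = c("sexavg", "female", "male"),
                           bridge_cm = 0.25) {
  stopifnot(inherits(map, "genetic_map"))
  track <- match.arg(track)
  cm_col <- paste0("cm_", track)
  out <- tibble(lg = character(), start_bp = numeric(), end_bp = numeric(),
                span_bp = numeric(), terminal = logical())
  for (lg in unique(map$positions$lg)) {
    p <- map$positions[map$positions$lg == lg, , drop = FALSE]
    if (nrow(p) < 2) next
    rate <- diff(p[[cm_col]]) / (diff(p$bp) / 1e6)
    low <- rate <= max_rate
    if (any(low) && any(!low)) {
      rl <- rle(low)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
      for (k in which(!rl$values)) {
        dcm <- p[[cm_col]][ends[k] + 1] - p[[cm_col]][starts[k]]
        if (dcm <= bridge_cm) low[starts[k]:ends[k]] <- TRUE
      }
    }
    r <- rle(low)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      span <- p$bp[i1 + 1] - p$bp[i0]
      if (span >= min_span) {
        out <- dplyr::bind_rows(out, tibble(
          lg = lg, start_bp = p$bp[i0], end_bp = p$bp[i1 + 1],
          span_bp = span,
          terminal = i0 == 1 || (i1 + 1) == nrow(p)))
      }
    }
  }
  out
}

#' Map the XY sex-determining locus
#'
#' Phenotypic sex is treated as a test marker at which every sire is
#' heterozygous (XY) and every dam homozygous (XX), so only sire meioses are
#' informative. For each marker, the recombination fraction with sex pools,
#' over sires, the minimum over the two possible marker-vs-Y phases of the
#' mismatch count between the sire's phased haplotype-of-origin indicators
#' and offspring sex. The peak is the marker (or run of tied markers) with
#' minimal recombination fraction.
#'
#' @param gm A [genotype_matrix()].
#' @param pedigree Offspring pedigree tibble (`id`, `sire`, `dam`).
#' @param map A `genetic_map` estimated on `gm` (provides cM positions).
#' @param sexes Tibble `id`, `sex` of offspring phenotypic sex (12/M male,
#'   11/F female).
#' @param min_informative Minimum sire meioses per marker for the marker to
#'   compete (default 20).
#' @return An object of class `sex_locus_result`: `status`, `lg`, `peak`
#'   tibble (tied run with bp, r, and cM on the three tracks), flanking
#'   markers, and the full per-marker `r` profile.
#' @export
map_sex_locus <- function(gm, pedigree, map, sexes, min_informative = 20) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(map, "genetic_map"))
  ped <- as_tibble(pedigree)
  ped <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
               ped$id %in% gm$samples, , drop = FALSE]
  sx <- normalize_sex(sexes$sex[match(ped$id, sexes$id)])
  ped <- ped[!is.na(sx), , drop = FALSE]
  sx <- sx[!is.na(sx)]
  if (nrow(ped) == 0 || length(unique(sx)) < 2) {
    return(structure(list(status = "unresolvable",
                          reason = "no informative sexed offspring (or all one sex)"),
                     class = "sex_locus_result"))
  }
  male01 <- as.integer(sx == "M")
  names(male01) <- ped$id

  m <- nrow(gm$markers)
  mism <- numeric(m); tot <- numeric(m)
  lg_idx <- split(seq_len(m), gm$markers$chrom)
  for (p in unique(ped$sire)) {
    res <- resolve_for_parent(gm, ped, p, "sire")
    if (!length(res$offspring)) next
    y <- male01[res$offspring]
    for (lg in names(lg_idx)) {
      gidx <- lg_idx[[lg]]
      inf_local <- which(gidx %in% res$het)
      if (!length(inf_local)) next
      A <- res$ind[, gidx[inf_local], drop = FALSE]
      H <- phase_parent(A)$hap
      ok <- !is.na(H)
      n_col <- colSums(ok)
      k_col <- colSums((H != matrix(y, nrow(H), ncol(H))) & ok, na.rm = TRUE)
      cols <- gidx[inf_local]
      mism[cols] <- mism[cols] + pmin(k_col, n_col - k_col)
      tot[cols] <- tot[cols] + n_col
    }
  }
  usable <- tot >= min_informative
  if (!any(usable)) {
    return(structure(list(status = "unresolvable",
                          reason = "no marker with enough sire-informative meioses"),
                     class = "sex_locus_result"))
  }
  r_hat <- rep(NA_real_, m)
  r_hat[usable] <- mism[usable] / tot[usable]
  r_min <- min(r_hat, na.rm = TRUE)
  # Tied markers form runs (contiguous among usable markers of an LG);
  # the peak is the run with the largest informative-meiosis support, so an
  # isolated weakly-informative zero cannot beat the true locus region.
  tied <- !is.na(r_hat) & r_hat <= r_min + 1e-12
  runs <- NULL
  for (lg in names(lg_idx)) {
    gidx <- lg_idx[[lg]]
    u <- gidx[!is.na(r_hat[gidx])]
    if (!length(u)) next
    tu <- tied[u]
    rl <- rle(tu)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      members <- u[starts[k]:ends[k]]
      runs <- dplyr::bind_rows(runs, tibble(
        lg = lg, first = members[1], last = members[length(members)],
        n_markers = length(members), support = sum(tot[members]),
        members = list(members)))
    }
  }
  best_run <- runs[order(-runs$support, -runs$n_markers), ][1, ]
  best_lg <- best_run$lg
  run_idx <- best_run$members[[1]]
  gidx <- lg_idx[[best_lg]]
  run <- match(run_idx, gidx)

  pos_tbl <- map$positions
  info <- function(i) {
    mk <- gm$markers$marker[i]
    j <- match(mk, pos_tbl$marker)
    tibble(marker = mk, lg = gm$markers$chrom[i], bp = gm$markers$pos[i],
           r = r_hat[i],
           cm_male = pos_tbl$cm_male[j], cm_female = pos_tbl$cm_female[j],
           cm_sexavg = pos_tbl$cm_sexavg[j])
  }
  peak <- info(run_idx)
  lo <- min(run); hi <- max(run)
  flank_idx <- c(if (lo > 1) gidx[lo - 1], if (hi < length(gidx)) gidx[hi + 1])
  mid <- run_idx[ceiling(length(run_idx) / 2)]
  structure(list(
    status = "ok", lg = best_lg,
    peak = peak,
    peak_bp = gm$markers$pos[mid],
    peak_cm_male = peak$cm_male[match(mid, run_idx)],
    peak_cm_female = peak$cm_female[match(mid, run_idx)],
    peak_cm_sexavg = peak$cm_sexavg[match(mid, run_idx)],
    r_at_peak = r_min,
    flanking = if (length(flank_idx)) info(flank_idx) else NULL,
    profile = tibble(marker = gm$markers$marker, lg = gm$markers$chrom,
                     bp = gm$markers$pos, r = r_hat, n = tot)),
    class = "sex_locus_result")
}

#' @export
print.sex_locus_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("<sex_locus_result> unresolvable:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<sex_locus_result> ", x$lg, " @ ", x$peak_bp, " bp (",
      round(x$peak_cm_sexavg, 2), " cM sex-averaged, r = ",
      signif(x$r_at_peak, 3), "; ", nrow(x$peak), " tied marker(s))\n", sep = "")
  invisible(x)
}

#' Tidy a sex-locus result
#' @param x A `sex_locus_result`.
#' @param ... Unused.
#' @return The tied-peak marker tibble (empty when unresolvable).
#' @method tidy sex_locus_result
#' @export
tidy.sex_locus_result <- function(x, ...) {
  if (x$status != "ok") return(tibble())
  x$peak
}
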