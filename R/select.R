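# Equidistant MAF-maximizing array selection: effect-prioritized picks
# followed by gap-filling on a fixed target lattice, per chromosome.

#' Array design configuration
#'
#' @param lg_interval Target spacing on linkage groups, bp (default 12000).
#' @param scaffold_interval Target spacing on unmapped scaffolds, bp
#'   (default 33000).
#' @param min_scaffold_len Minimum scaffold length to receive picks, bp
#'   (default 50000).
#' @param effect_min_spacing Minimum spacing between effect-prioritized picks,
#'   bp (default 10000).
#' @param effect_budget Maximum number of effect-prioritized picks
#'   (default 10000).
#' @param window_half_width Half-width of the selection window around each
#'   lattice target, bp; default half the applicable interval.
#' @param moving_grid When `TRUE`, re-anchor the target lattice after each
#'   pick instead of using a fixed lattice (default FALSE).
#'
#' @return An object of class `array_design_config`.
#' @export
array_design_config <- function(lg_interval = 12000, scaffold_interval = 33000,
                                min_scaffold_len = 50000,
                                effect_min_spacing = 10000,
                                effect_budget = 10000,
                                window_half_width = NULL,
                                moving_grid = FALSE) {
  assert_that(all(c(lg_interval, scaffold_interval, min_scaffold_len,
                    effect_min_spacing, effect_budget) > 0),
              "design parameters must be > 0")
  if (!is.null(window_half_width)) {
    assert_that(window_half_width <= max(lg_interval, scaffold_interval),
                "window_half_width must not exceed the applicable interval")
  }
  structure(list(lg_interval = lg_interval,
                 scaffold_interval = scaffold_interval,
                 min_scaffold_len = min_scaffold_len,
                 effect_min_spacing = effect_min_spacing,
                 effect_budget = effect_budget,
                 window_half_width = window_half_width,
                 moving_grid = moving_grid),
            class = "array_design_config")
}

#' Effect-prioritized candidate selection
#'
#' Greedy left-to-right scan over HIGH/MODERATE-impact candidates per
#' chromosome: a candidate is taken when it lies at least
#' `effect_min_spacing` bp from the last taken pick on that chromosome. When
#' the greedy set exceeds `effect_budget`, picks are kept in order of higher
#' MAF, then lower position.
#'
#' @param candidates Tibble with `marker`, `chrom`, `pos`, `maf`, sorted by
#'   (chrom, pos).
#' @param annotations Tibble with `marker`, `impact` (HIGH/MODERATE picked).
#' @param config An [array_design_config()].
#' @return Tibble of chosen candidates (subset of `candidates`).
#' @export
select_effect_candidates <- function(candidates, annotations,
                                     config = array_design_config()) {
  eligible <- dplyr::semi_join(
    candidates,
    dplyr::filter(annotations, toupper(.data$impact) %in% c("HIGH", "MODERATE")),
    by = "marker")
  if (nrow(eligible) == 0) return(eligible)
  eligible <- dplyr::arrange(eligible, .data$chrom, .data$pos)
  taken <- unlist(lapply(split(seq_len(nrow(eligible)), eligible$chrom),
                         function(idx) {
    pos <- eligible$pos[idx]
    keep <- logical(length(idx))
    last <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - last >= config$effect_min_spacing) {
        keep[k] <- TRUE
        last <- pos[k]
      }
    }
    idx[keep]
  }), use.names = FALSE)
  out <- eligible[sort(taken), , drop = FALSE]
  if (nrow(out) > config$effect_budget) {
    ord <- order(-out$maf, out$pos)
    out <- out[sort(ord[seq_len(config$effect_budget)]), , drop = FALSE]
  }
  out
}

#' Fill distribution gaps on one chromosome
#'
#' Lays target positions on a fixed lattice (`interval`, `2*interval`, ...,
#' up to the chromosome length). A target already covered by a selected
#' marker within `window_half_width` bp is skipped; otherwise the candidate
#' inside the window with the highest MAF is added (ties: closest to the
#' target, then smaller position). Targets with an empty window are reported
#' unfilled.
#'
#' @param candidates Tibble (`marker`, `chrom`, `pos`, `maf`) for one
#'   chromosome, sorted by pos.
#' @param already_selected Tibble with at least `pos` (may be empty).
#' @param interval Lattice spacing, bp.
#' @param window_half_width Selection window half-width, bp (default
#'   `interval / 2`).
#' @param chrom_length Chromosome length, bp (default: last candidate pos).
#' @param moving_grid Re-anchor the lattice at the last satisfied position
#'   after each target (default FALSE).
#' @return List with `added` (tibble of new picks) and `unfilled` (numeric
#'   vector of uncovered target positions).
#' @export
fill_gaps <- function(candidates, already_selected, interval,
                      window_half_width = interval / 2,
                      chrom_length = NULL, moving_grid = FALSE) {
  assert_that(length(unique(candidates$chrom)) <= 1,
              "fill_gaps works on one chromosome at a time")
  chrom_length <- chrom_length %||% (if (nrow(candidates)) max(candidates$pos) else 0)
  sel_pos <- sort(c(already_selected$pos %||% numeric(0)))
  cand <- dplyr::arrange(candidates, .data$pos)
  added <- cand[0, , drop = FALSE]
  unfilled <- numeric(0)

  pick_at <- function(target, sel_pos) {
    if (length(sel_pos) &&
        min(abs(sel_pos - target)) <= window_half_width) return(NULL)
    inw <- which(cand$pos >= target - window_half_width &
                   cand$pos <= target + window_half_width &
                   !(cand$pos %in% sel_pos))
    if (!length(inw)) return(NA)
    w <- cand[inw, , drop = FALSE]
    ord <- order(-w$maf, abs(w$pos - target), w$pos)
    w[ord[1], , drop = FALSE]
  }

  if (!moving_grid) {
    targets <- seq(interval, chrom_length, by = interval)
    for (t in targets) {
      res <- pick_at(t, c(sel_pos, added$pos))
      if (is.null(res)) next
      if (all(is.na(res))) { unfilled <- c(unfilled, t); next }
      added <- dplyr::bind_rows(added, res)
    }
  } else {
    anchor <- 0
    while (anchor + interval <= chrom_length) {
      t <- anchor + interval
      res <- pick_at(t, c(sel_pos, added$pos))
      if (is.null(res)) {
        covering <- c(sel_pos, added$pos)
        anchor <- max(covering[abs(covering - t) <= window_half_width])
      } else if (all(is.na(res))) {
        unfilled <- c(unfilled, t)
        anchor <- t
      } else {
        added <- dplyr::bind_rows(added, res)
        anchor <- res$pos
      }
    }
  }
  list(added = added, unfilled = unfilled)
}

#' End-to-end array selection
#'
#' Effect-prioritized picks first, then per-linkage-group gap filling at
#' `lg_interval`, then per unmapped scaffold of length at least
#' `min_scaffold_len` at `scaffold_interval`. A manually curated include
#' list (e.g. mitochondrial markers) is appended with provenance
#' `MITO_MANUAL`. When a `reject` list is given (markers failing external
#' probe scoring), rejected picks are dropped and their windows refilled in
#' a second pass.
#'
#' @param candidates Tibble `marker`, `chrom`, `pos`, `maf` of filtered
#'   variants (e.g. `tidy()` of a filter result's kept set).
#' @param annotations Annotation tibble (`marker`, `impact`); may be empty.
#' @param layout Genome layout tibble (see [genome_layout()]).
#' @param config An [array_design_config()].
#' @param include Character vector of marker ids appended manually.
#' @param reject Character vector of marker ids rejected by probe scoring.
#' @return An object of class `selection_result`: `chosen` tibble (`marker`,
#'   `chrom`, `pos`, `maf`, `provenance`), `unfilled` targets tibble, and a
#'   per-chromosome `spacing` summary.
#' @export
select_array <- function(candidates, annotations = NULL, layout,
                         config = array_design_config(),
                         include = character(0), reject = character(0)) {
  candidates <- dplyr::arrange(as_tibble(candidates), .data$chrom, .data$pos)
  missing_chrom <- setdiff(unique(candidates$chrom), layout$name)
  assert_that(length(missing_chrom) == 0,
              paste0("layout missing chromosome(s): ",
                     paste(missing_chrom, collapse = ", ")),
              "onilmap_consistency_error")
  if (is.null(annotations)) annotations <- tibble(marker = character(),
                                                  impact = character())
  effect <- select_effect_candidates(candidates, annotations, config)
  effect <- effect[!effect$marker %in% reject, , drop = FALSE]
  chosen <- dplyr::mutate(effect, provenance = "EFFECT")
  unfilled <- tibble(chrom = character(), target = numeric())

  fill_chrom <- function(ch, interval, chosen, candidates) {
    whw <- config$window_half_width %||% (interval / 2)
    cand_ch <- candidates[candidates$chrom == ch & !candidates$marker %in% reject, ,
                          drop = FALSE]
    sel_ch <- chosen[chosen$chrom == ch, , drop = FALSE]
    res <- fill_gaps(cand_ch, sel_ch, interval, whw,
                     chrom_length = layout$length_bp[layout$name == ch],
                     moving_grid = config$moving_grid)
    list(added = dplyr::mutate(res$added, provenance = "GAPFILL"),
         unfilled = tibble(chrom = ch, target = res$unfilled))
  }

  for (ch in layout$name[layout$assigned]) {
    res <- fill_chrom(ch, config$lg_interval, chosen, candidates)
    chosen <- dplyr::bind_rows(chosen, res$added)
    unfilled <- dplyr::bind_rows(unfilled, res$unfilled)
  }
  scafs <- layout[!layout$assigned & layout$length_bp >= config$min_scaffold_len, ]
  for (ch in scafs$name) {
    res <- fill_chrom(ch, config$scaffold_interval, chosen, candidates)
    chosen <- dplyr::bind_rows(chosen, res$added)
    unfilled <- dplyr::bind_rows(unfilled, res$unfilled)
  }
  if (length(include)) {
    inc <- candidates[candidates$marker %in% include &
                        !candidates$marker %in% chosen$marker, , drop = FALSE]
    chosen <- dplyr::bind_rows(chosen, dplyr::mutate(inc, provenance = "MITO_MANUAL"))
  }
  chosen <- dplyr::arrange(chosen, .data$chrom, .data$pos)

  spacing <- chosen |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_spacing = mean(diff(sort(.data$pos))),
                     max_spacing = ifelse(dplyr::n() > 1,
                                          max(diff(sort(.data$pos))), NA_real_),
                     .groups = "drop")
  structure(list(chosen = chosen, unfilled = unfilled, spacing = spacing,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", nrow(x$chosen), " markers chosen (",
      paste(names(table(x$chosen$provenance)),
            table(x$chosen$provenance), sep = "=", collapse = ", "),
      "); ", nrow(x$unfilled), " unfilled targets\n", sep = "")
  invisible(x)
}

#' Tidy a selection result
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The chosen-marker tibble with provenance.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$chosen

#' One-line summary of a selection result
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return One-row tibble with counts by provenance and spacing summary.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(n_chosen = nrow(x$chosen),
         n_effect = sum(x$chosen$provenance == "EFFECT"),
         n_gapfill = sum(x$chosen$provenance == "GAPFILL"),
         n_manual = sum(x$chosen$provenance == "MITO_MANUAL"),
         n_unfilled = nrow(x$unfilled),
         mean_spacing = mean(x$spacing$mean_spacing, na.rm = TRUE))
}
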