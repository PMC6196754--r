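# Per-linkage-group map statistics (marker numbers, lengths, F:M ratios,
# densities, Marey correlations) and their totals/averages.

#' Per-LG summary of a genetic map
#'
#' One row per linkage group: number of SNPs, physical length (Mb), female /
#' male / sex-averaged lengths (cM), F:M ratio (2 decimals), marker density
#' per Mb and per cM of each track, and the Marey correlation (genetic vs
#' physical position) per track.
#'
#' @param map A `genetic_map`.
#' @param layout Optional genome layout; when given, physical lengths come
#'   from the assembly rather than the marker span.
#' @param cor_method Correlation method for the Marey correlation:
#'   `"pearson"` (default, product-moment) or `"spearman"` (rank).
#' @return A tibble, one row per LG, plus attribute-free columns only.
#' @export
map_summary <- function(map, layout = NULL,
                        cor_method = c("pearson", "spearman")) {
  stopifnot(inherits(map, "genetic_map"))
  cor_method <- match.arg(cor_method)
  per <- map$positions |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      span_mb = (max(.data$bp) - min(.data$bp)) / 1e6,
      female_cm = max(.data$cm_female),
      male_cm = max(.data$cm_male),
      sexavg_cm = max(.data$cm_sexavg),
      cor_female = suppressWarnings(
        stats::cor(.data$bp, .data$cm_female, method = cor_method)),
      cor_male = suppressWarnings(
        stats::cor(.data$bp, .data$cm_male, method = cor_method)),
      cor_sexavg = suppressWarnings(
        stats::cor(.data$bp, .data$cm_sexavg, method = cor_method)),
      .groups = "drop")
  if (!is.null(layout)) {
    per$phys_mb <- layout$length_bp[match(per$lg, layout$name)] / 1e6
  } else {
    per$phys_mb <- per$span_mb
  }
  per |>
    dplyr::mutate(
      fm_ratio = ifelse(.data$male_cm > 0,
                        round_half_up(.data$female_cm / .data$male_cm, 2),
                        NA_real_),
      density_per_mb = .data$n_snps / .data$phys_mb,
      density_per_cm_female = ifelse(.data$female_cm > 0,
                                     .data$n_snps / .data$female_cm, NA_real_),
      density_per_cm_male = ifelse(.data$male_cm > 0,
                                   .data$n_snps / .data$male_cm, NA_real_),
      density_per_cm_sexavg = ifelse(.data$sexavg_cm > 0,
                                     .data$n_snps / .data$sexavg_cm, NA_real_)) |>
    dplyr::select("lg", "n_snps", "phys_mb", "female_cm", "male_cm",
                  "sexavg_cm", "fm_ratio", "density_per_mb",
                  dplyr::starts_with("density_per_cm"),
                  dplyr::starts_with("cor_"))
}

#' Totals and averages of a per-LG map summary
#'
#' Column totals (marker count, physical length, per-track cM sums) and
#' per-LG averages, plus the overall female:male factor computed from the
#' total lengths. Accepts any tibble with columns `n_snps`, `phys_mb`,
#' `female_cm`, `male_cm`, `sexavg_cm` — e.g. the output of
#' [map_summary()], or a published per-LG table.
#'
#' @param per_lg Per-LG summary tibble.
#' @return One-row tibble with totals, averages and the F:M factor
#'   (2 decimals).
#' @export
map_table_totals <- function(per_lg) {
  assert_that(all(c("n_snps", "phys_mb", "female_cm", "male_cm", "sexavg_cm")
                  %in% names(per_lg)),
              "per-LG table must have n_snps, phys_mb, female_cm, male_cm, sexavg_cm")
  n_lg <- nrow(per_lg)
  tf <- sum(per_lg$female_cm); tm <- sum(per_lg$male_cm)
  tibble(
    n_lgs = n_lg,
    total_snps = sum(per_lg$n_snps),
    total_phys_mb = sum(per_lg$phys_mb),
    total_female_cm = tf,
    total_male_cm = tm,
    total_sexavg_cm = sum(per_lg$sexavg_cm),
    fm_factor = round_half_up(tf / tm, 2),
    mean_snps_per_lg = round_half_up(sum(per_lg$n_snps) / n_lg, 0),
    mean_female_cm = round_half_up(tf / n_lg, 2),
    mean_male_cm = round_half_up(tm / n_lg, 2),
    mean_sexavg_cm = round_half_up(sum(per_lg$sexavg_cm) / n_lg, 2),
    mean_fm_ratio = if ("fm_ratio" %in% names(per_lg))
      round_half_up(mean(per_lg$fm_ratio, na.rm = TRUE), 2) else NA_real_)
}
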