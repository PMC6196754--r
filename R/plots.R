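# ggplot2 views of the main result types.

#' Marey plot of a genetic map
#'
#' Genetic position (cM) against physical position (Mb) per linkage group,
#' one curve per sex track; the slope is the local recombination rate, flat
#' stretches are recombination deserts.
#'
#' @param object A `genetic_map`.
#' @param tracks Which tracks to draw (default all three).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object,
                                 tracks = c("female", "male", "sexavg"),
                                 ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("cm_"),
                        names_to = "track", values_to = "cm",
                        names_prefix = "cm_") |>
    dplyr::filter(.data$track %in% tracks)
  ggplot2::ggplot(long, ggplot2::aes(.data$bp / 1e6, .data$cm,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$lg), scales = "free") +
    ggplot2::scale_colour_manual(values = c(female = "#c0392b",
                                            male = "#2c3e94",
                                            sexavg = "black")) +
    ggplot2::labs(x = "physical position (Mb)", y = "genetic position (cM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar-chart summaries of genotype QC metrics
#'
#' Binned distributions of Hardy-Weinberg p-values, call rate, MAF and
#' cluster category for an array QC run.
#'
#' @param object A `qc_summary`.
#' @param ... Unused.
#' @return A ggplot (patch of four panels via facets).
#' @method autoplot qc_summary
#' @export
autoplot.qc_summary <- function(object, ...) {
  b <- object$bins
  long <- dplyr::bind_rows(
    dplyr::mutate(b$hwe_p, metric = "HW p-value", bin = as.character(.data$bin)),
    dplyr::mutate(b$call_rate, metric = "call rate", bin = as.character(.data$bin)),
    dplyr::mutate(b$maf, metric = "MAF", bin = as.character(.data$bin)),
    dplyr::mutate(b$category, metric = "category",
                  bin = .data$category, category = NULL))
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sex-locus association profile
#'
#' Recombination fraction with the sex pseudo-marker along the genome, with
#' the peak run highlighted.
#'
#' @param object A `sex_locus_result`.
#' @param ... Unused.
#' @return A ggplot, or NULL when the locus was unresolvable.
#' @method autoplot sex_locus_result
#' @export
autoplot.sex_locus_result <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  prof <- object$profile[!is.na(object$profile$r), , drop = FALSE]
  ggplot2::ggplot(prof, ggplot2::aes(.data$bp / 1e6, .data$r)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_point(data = object$peak, colour = "#c0392b") +
    ggplot2::facet_wrap(ggplot2::vars(.data$lg), scales = "free_x") +
    ggplot2::labs(x = "physical position (Mb)",
                  y = "recombination fraction with sex") +
    ggplot2::theme_minimal()
}
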