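# Array-genotype quality metrics and the cluster-category classification
# computable from genotype codes (intensity-free subset).

#' QC thresholds
#'
#' @param snp_call_rate_min Minimum per-SNP call rate (default 0.97,
#'   inclusive).
#' @param sample_call_rate_min Minimum per-sample call rate (default 0.97,
#'   inclusive).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.97, sample_call_rate_min = 0.97) {
  assert_that(snp_call_rate_min > 0 && snp_call_rate_min <= 1 &&
                sample_call_rate_min > 0 && sample_call_rate_min <= 1,
              "call-rate thresholds must be in (0, 1]")
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min),
            class = "qc_thresholds")
}

#' Per-sample call rates
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return Tibble `sample`, `call_rate`, `pass` (inclusive threshold).
#' @export
sample_call_rates <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_that(nrow(gm$markers) > 0, "empty genotype matrix")
  cr <- unname(rowMeans(gm$codes >= 0L))
  tibble(sample = gm$samples, call_rate = cr,
         pass = cr >= thresholds$sample_call_rate_min)
}

#' Classify a SNP into a cluster category from genotype counts
#'
#' Intensity-free analog of the vendor's cluster categories: call rate below
#' threshold wins; otherwise all three genotype classes present is
#' `PolyHighResolution`; one homozygote class plus heterozygotes is
#' `NoMinorHom`; a single homozygote class alone is `MonoHighResolution`;
#' remaining patterns (het-only, two homozygote classes without hets,
#' all-missing) are `Other`. The off-target-variant category needs raw
#' intensities and is out of scope.
#'
#' @param n0,n1,n2,n_missing Genotype counts (vectors; recycled).
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of categories.
#' @examples
#' classify_snp(50, 30, 20, 1)  # PolyHighResolution
#' classify_snp(80, 20, 0, 0)   # NoMinorHom
#' @export
classify_snp <- function(n0, n1, n2, n_missing = 0,
                         thresholds = qc_thresholds()) {
  ln <- max(length(n0), length(n1), length(n2), length(n_missing))
  n0 <- rep_len(n0, ln); n1 <- rep_len(n1, ln); n2 <- rep_len(n2, ln)
  n_missing <- rep_len(n_missing, ln)
  assert_that(all(c(n0, n1, n2, n_missing) >= 0), "counts must be >= 0")
  tot <- n0 + n1 + n2 + n_missing
  assert_that(all(tot > 0), "total count must be > 0")
  called <- n0 + n1 + n2
  cr <- called / tot
  n_hom_classes <- (n0 > 0) + (n2 > 0)
  out <- rep("Other", ln)
  poly <- n0 > 0 & n1 > 0 & n2 > 0
  nmh <- n_hom_classes == 1 & n1 > 0
  mono <- n_hom_classes == 1 & n1 == 0
  out[mono] <- "MonoHighResolution"
  out[nmh] <- "NoMinorHom"
  out[poly] <- "PolyHighResolution"
  out[cr < thresholds$snp_call_rate_min] <- "CallRateBelowThreshold"
  out[called == 0] <- "Other"
  out
}

# Fixed, documented bin edges so summaries are comparable across runs.
qc_bins <- list(
  hwe_p = c(0, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1),
  call_rate = c(0, 0.85, 0.90, 0.95, 0.97, 0.99, 1),
  maf = seq(0, 0.5, by = 0.05)
)

#' Per-SNP QC summary of a genotype matrix
#'
#' One record per marker: genotype counts, call rate, MAF, exact
#' Hardy-Weinberg p-value, cluster category, and whether the marker enters
#' the mapping-ready subset (`PolyHighResolution` or `NoMinorHom`). Also
#' returns binned distributions of the metrics on fixed bin edges.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param exclude_samples Optional sample ids dropped before computing SNP
#'   metrics (e.g. an intensity-QC exclusion list).
#' @return An object of class `qc_summary`: `snp` tibble, `samples` tibble
#'   (call rates), `bins` (named list of binned count tibbles).
#' @export
qc_summary <- function(gm, thresholds = qc_thresholds(),
                       exclude_samples = character(0)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !gm$samples %in% exclude_samples
  g <- gm$codes[keep, , drop = FALSE]
  n0 <- colSums(g == 0L); n1 <- colSums(g == 1L); n2 <- colSums(g == 2L)
  nm <- colSums(g == -1L)
  called <- n0 + n1 + n2
  cr <- called / (called + nm)
  alt <- n1 + 2 * n2
  maf <- ifelse(called > 0, pmin(alt, 2 * called - alt) / (2 * called), NA_real_)
  hwe_p <- rep(NA_real_, length(n0))
  ok <- called > 0
  hwe_p[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
  category <- classify_snp(n0, n1, n2, nm, thresholds)
  snp <- dplyr::mutate(gm$markers,
                       n0 = n0, n1 = n1, n2 = n2, n_missing = nm,
                       call_rate = cr, maf = maf, hwe_p = hwe_p,
                       category = category,
                       mapping_ready = category %in%
                         c("PolyHighResolution", "NoMinorHom"))
  bin_count <- function(x, edges) {
    cut_lab <- cut(x, breaks = edges, include.lowest = TRUE, right = TRUE)
    dplyr::count(tibble(bin = cut_lab), .data$bin, .drop = FALSE)
  }
  bins <- list(
    hwe_p = bin_count(hwe_p, qc_bins$hwe_p),
    call_rate = bin_count(cr, qc_bins$call_rate),
    maf = bin_count(maf, qc_bins$maf),
    category = dplyr::count(snp, .data$category)
  )
  structure(list(snp = snp,
                 samples = sample_call_rates(gm, thresholds),
                 bins = bins, thresholds = thresholds),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("<qc_summary> ", nrow(x$snp), " markers, ", nrow(x$samples), " samples\n",
      sep = "")
  print(x$bins$category)
  invisible(x)
}

#' Tidy a QC summary
#' @param x A `qc_summary`.
#' @param ... Unused.
#' @return The per-SNP metric tibble.
#' @method tidy qc_summary
#' @export
tidy.qc_summary <- function(x, ...) x$snp

#' One-line summary of genotype QC
#' @param x A `qc_summary`.
#' @param ... Unused.
#' @return One-row tibble: marker/sample counts, pass rates, mapping-ready
#'   count.
#' @method glance qc_summary
#' @export
glance.qc_summary <- function(x, ...) {
  tibble(n_markers = nrow(x$snp),
         n_samples = nrow(x$samples),
         samples_pass = sum(x$samples$pass),
         sample_retention_pct = round_half_up(100 * mean(x$samples$pass), 2),
         poly_high_res_pct = round_half_up(
           100 * mean(x$snp$category == "PolyHighResolution"), 2),
         n_mapping_ready = sum(x$snp$mapping_ready))
}
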