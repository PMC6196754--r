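#' Genome layout table
#'
#' A genome layout is a tibble describing the chromosomes (linkage groups) and
#' unplaced scaffolds of an assembly: one row per sequence with its name,
#' length in base pairs, and whether it is assigned to a linkage group.
#'
#' @param name Character vector of unique sequence names.
#' @param length_bp Positive integer vector of sequence lengths (bp).
#' @param assigned Logical vector: `TRUE` for sequences assigned to a linkage
#'   group, `FALSE` for unplaced scaffolds.
#'
#' @return A tibble with columns `name`, `length_bp`, `assigned`.
#' @examples
#' genome_layout(c("LG01", "scaffold_1"), c(35e6, 120e3), c(TRUE, FALSE))
#' @export
genome_layout <- function(name, length_bp, assigned = rep(TRUE, length(name))) {
  assert_that(!anyDuplicated(name), "genome layout names must be unique")
  assert_that(all(length_bp > 0), "genome layout lengths must be > 0")
  assert_that(length(name) == length(length_bp) && length(name) == length(assigned),
              "genome layout columns must have equal length")
  tibble(name = as.character(name),
         length_bp = as.numeric(length_bp),
         assigned = as.logical(assigned))
}

default_genome_layout <- function() {
  genome_layout(
    name = c("LG01", "LG02", "LG03", "scaffold_1", "scaffold_2"),
    length_bp = c(35e6, 30e6, 40e6, 120e3, 30e3),
    assigned = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Piecewise-linear Marey curve
#'
#' A Marey curve maps physical position (bp) to cumulative genetic position
#' (cM) along one chromosome for one sex. The simulator uses sigmoid-shaped
#' curves with zero-recombination "deserts" at the chromosome ends, emulating
#' the subtelo-acrocentric recombination profile of tilapia linkage groups.
#'
#' @param length_bp Chromosome length in bp.
#' @param total_cm Total map length in cM.
#' @param desert_bp Length of the terminal zero-recombination regions (bp);
#'   clamped to at most 40% of the chromosome on each side.
#'
#' @return A tibble of knots with columns `bp` and `cm`, non-decreasing in
#'   both, starting at (0, 0).
#' @export
marey_curve <- function(length_bp, total_cm, desert_bp = 5e6) {
  assert_that(length_bp > 0 && total_cm >= 0, "invalid Marey curve parameters")
  d <- min(desert_bp, 0.4 * length_bp)
  inner <- length_bp - 2 * d
  # Sigmoid interior: slow-fast-slow through two interior knots.
  bp <- c(0, d, d + 0.3 * inner, d + 0.7 * inner, length_bp - d, length_bp)
  cm <- c(0, 0, 0.2, 0.8, 1, 1) * total_cm
  tibble(bp = bp, cm = cm)
}

marey_cm_at <- function(curve, bp) {
  stats::approx(curve$bp, curve$cm, xout = bp, rule = 2, ties = "ordered")$y
}

marey_bp_at <- function(curve, cm) {
  stats::approx(curve$cm, curve$bp, xout = cm, rule = 2, ties = "ordered")$y
}

validate_marey <- function(curve) {
  assert_that(nrow(curve) >= 2 && curve$bp[1] == 0 && curve$cm[1] == 0,
              "Marey curve must start at (0, 0)")
  assert_that(!is.unsorted(curve$bp) && !is.unsorted(curve$cm),
              "Marey curve must be non-decreasing")
  invisible(curve)
}

#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic-data generator: the
#' genome layout, candidate-variant density, founder allele-frequency law,
#' per-sex true genetic maps, the XY sex-determining locus, family structure,
#' and the noise model. Defaults emulate the design of the study the package
#' reproduces: ~32 resequenced founders, 41 factorial full-sib families
#' averaging ~16.8 offspring, female maps 1.2x longer than male maps with
#' sigmoid Marey profiles and 5 Mb terminal recombination deserts, and an XY
#' locus on the largest linkage group.
#'
#' @param genome Genome layout tibble (see [genome_layout()]).
#' @param n_founders Number of discovery founders (default 32).
#' @param site_density_bp Mean spacing of candidate variant sites in bp;
#'   sites are Poisson-placed (default 2000).
#' @param maf_range Range of the founder minor-allele frequency law,
#'   `Uniform(min, max)` (default `c(0.02, 0.5)`).
#' @param male_cm_per_mb Genome-wide male recombination rate used to set the
#'   total male map length of each linkage group (default 1.57 cM/Mb).
#' @param fm_ratio Female:male total map length ratio (default 1.2).
#' @param desert_bp Terminal zero-recombination span per chromosome end
#'   (default 5e6 bp).
#' @param sex_locus List `list(chrom =, pos =)` placing the XY locus;
#'   `NULL` (default) puts it on the largest assigned linkage group at 86%
#'   of its length (LG03 at 34.5 Mb under the default genome, emulating the
#'   amh region position).
#' @param n_families Number of full-sib families (default 41).
#' @param offspring_per_family Either a single number used as the mean of a
#'   Poisson family-size law (truncated at `min_family`), or a vector of
#'   exact family sizes (default 16.81).
#' @param min_family Minimum simulated family size (default 8).
#' @param n_sires,n_dams Size of the factorial parent pools (default 17, 16).
#' @param error_rate Genotyping error rate: each offspring genotype is flipped
#'   to a uniformly chosen different code with this probability (default 0.002).
#' @param missing_rate Genotype missing rate (default 0.01).
#' @param noise_scope `"offspring"` (default) applies the error/missing model
#'   to offspring genotypes only; `"all"` also noises parents' array genotypes.
#' @param depth_mean Mean of the per-founder per-site Poisson read-depth law
#'   (default 20).
#' @param gq_below30_frac Fraction of founder genotype-quality values drawn
#'   below 30 (default 0.10).
#' @param qual_below20_frac Fraction of sites with phred site quality <= 20
#'   (default 0.05).
#' @param indel_frac,mnp_frac Fractions of candidate sites emitted as INDEL /
#'   MNP records (defaults 0.05, 0.01).
#' @param atcg_frac Fraction of SNP sites with A/T or C/G alleles
#'   (default 0.05).
#' @param multiallelic_frac Fraction of SNP sites with two alternate alleles
#'   (default 0.02).
#' @param seed Integer seed; every random draw in the generator flows from it.
#'
#' @return An object of class `sim_config` (a named list, validated).
#' @examples
#' cfg <- sim_config(seed = 1, n_families = 4, offspring_per_family = 10)
#' cfg$genome
#' @export
sim_config <- function(genome = default_genome_layout(),
                       n_founders = 32,
                       site_density_bp = 2000,
                       maf_range = c(0.02, 0.5),
                       male_cm_per_mb = 1.57,
                       fm_ratio = 1.2,
                       desert_bp = 5e6,
                       sex_locus = NULL,
                       n_families = 41,
                       offspring_per_family = 16.81,
                       min_family = 8,
                       n_sires = 17,
                       n_dams = 16,
                       error_rate = 0.002,
                       missing_rate = 0.01,
                       noise_scope = c("offspring", "all"),
                       depth_mean = 20,
                       gq_below30_frac = 0.10,
                       qual_below20_frac = 0.05,
                       indel_frac = 0.05,
                       mnp_frac = 0.01,
                       atcg_frac = 0.05,
                       multiallelic_frac = 0.02,
                       seed = 1L) {
  noise_scope <- match.arg(noise_scope)
  if (is.null(sex_locus)) {
    lg_rows <- genome[genome$assigned, , drop = FALSE]
    assert_that(nrow(lg_rows) > 0, "genome needs at least one assigned LG",
                "onilmap_config_error")
    big <- which.max(lg_rows$length_bp)
    sex_locus <- list(chrom = lg_rows$name[big],
                      pos = round(0.8625 * lg_rows$length_bp[big]))
  }
  assert_that(error_rate >= 0 && error_rate < 0.5, "error_rate must be in [0, 0.5)")
  assert_that(missing_rate >= 0 && missing_rate < 0.5, "missing_rate must be in [0, 0.5)")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "allele frequencies must lie in (0, 0.5]")
  assert_that(sex_locus$chrom %in% genome$name,
              "sex locus chromosome absent from genome layout", "onilmap_config_error")
  assert_that(sex_locus$pos >= 1 &&
                sex_locus$pos <= genome$length_bp[genome$name == sex_locus$chrom],
              "sex locus outside genome", "onilmap_config_error")

  lgs <- genome[genome$assigned, , drop = FALSE]
  maps <- lapply(seq_len(nrow(lgs)), function(i) {
    m_cm <- male_cm_per_mb * lgs$length_bp[i] / 1e6
    list(
      male = validate_marey(marey_curve(lgs$length_bp[i], m_cm, desert_bp)),
      female = validate_marey(marey_curve(lgs$length_bp[i], m_cm * fm_ratio, desert_bp))
    )
  })
  names(maps) <- lgs$name

  structure(list(
    genome = genome, n_founders = n_founders,
    site_density_bp = site_density_bp, maf_range = maf_range,
    male_cm_per_mb = male_cm_per_mb, fm_ratio = fm_ratio,
    desert_bp = desert_bp, true_maps = maps, sex_locus = sex_locus,
    n_families = n_families, offspring_per_family = offspring_per_family,
    min_family = min_family, n_sires = n_sires, n_dams = n_dams,
    error_rate = error_rate, missing_rate = missing_rate,
    noise_scope = noise_scope, depth_mean = depth_mean,
    gq_below30_frac = gq_below30_frac, qual_below20_frac = qual_below20_frac,
    indel_frac = indel_frac, mnp_frac = mnp_frac, atcg_frac = atcg_frac,
    multiallelic_frac = multiallelic_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  lgs <- x$genome[x$genome$assigned, ]
  cat("<sim_config>\n")
  cat("  genome: ", nrow(lgs), " LGs (",
      paste0(round(lgs$length_bp / 1e6, 1), collapse = "/"), " Mb), ",
      sum(!x$genome$assigned), " unplaced scaffolds\n", sep = "")
  cat("  founders:", x$n_founders,
      " | families:", x$n_families, "\n")
  cat("  F:M ratio:", x$fm_ratio, "| sex locus:", x$sex_locus$chrom,
      "@", x$sex_locus$pos, "\n")
  cat("  error:", x$error_rate, "missing:", x$missing_rate,
      "seed:", x$seed, "\n")
  invisible(x)
}
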