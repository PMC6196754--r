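# Published-table-style summaries and pipeline orchestration.

#' Variant density per chromosome
#'
#' bp-per-variant rates per sequence plus a total row, in the style of an
#' assembly-assignment summary table. Rates round half away from zero; rows
#' with zero variants report an undefined (NA) rate, never a division error.
#'
#' @param layout Tibble `name`, `length_bp` (a genome layout works).
#' @param counts Tibble `name`, `variants`.
#' @return Tibble `name`, `length_bp`, `variants`, `bp_per_variant`
#'   (rounded) and `bp_per_variant_raw`, with a final `Total` row.
#' @examples
#' density_summary(tibble::tibble(name = "LG01", length_bp = 31194787),
#'                 tibble::tibble(name = "LG01", variants = 2571))
#' @export
density_summary <- function(layout, counts) {
  assert_that(all(counts$variants >= 0), "variant counts must be >= 0")
  x <- dplyr::left_join(as_tibble(layout)[, c("name", "length_bp")],
                        as_tibble(counts), by = "name")
  x$variants[is.na(x$variants)] <- 0
  rate <- ifelse(x$variants > 0, x$length_bp / x$variants, NA_real_)
  tot <- tibble(name = "Total", length_bp = sum(x$length_bp),
                variants = sum(x$variants))
  tot_rate <- ifelse(tot$variants > 0, tot$length_bp / tot$variants, NA_real_)
  dplyr::bind_rows(
    dplyr::mutate(x, bp_per_variant = round_half_up(rate),
                  bp_per_variant_raw = rate),
    dplyr::mutate(tot, bp_per_variant = round_half_up(tot_rate),
                  bp_per_variant_raw = tot_rate))
}

#' Annotation category summary
#'
#' Counts and percentages per annotation category against a fixed
#' denominator, in the style of an array-content annotation table. When a
#' long annotation table is supplied, one highest-impact annotation per
#' marker is kept before counting (categories must then be ordered by
#' `category_priority`).
#'
#' @param annotations Either a pre-tabulated tibble `category`, `count`, or
#'   a long tibble `marker`, `category` (one row per annotation).
#' @param denominator Total count percentages are taken against.
#' @param category_priority Optional character vector; when collapsing a
#'   long table, the earliest listed category per marker wins.
#' @return Tibble `category`, `count`, `percent` (2 decimals, half away from
#'   zero) and `percent_raw`.
#' @examples
#' annotation_summary(tibble::tibble(category = "Intron variant",
#'                                   count = 21581), 58446)
#' @export
annotation_summary <- function(annotations, denominator,
                               category_priority = NULL) {
  assert_that(denominator > 0, "denominator must be > 0")
  x <- as_tibble(annotations)
  if (!"count" %in% names(x)) {
    assert_that(all(c("marker", "category") %in% names(x)),
                "long annotation tables need marker and category columns")
    if (!is.null(category_priority)) {
      x$..rank <- match(x$category, category_priority)
      x <- x |>
        dplyr::group_by(.data$marker) |>
        dplyr::slice_min(.data$..rank, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
    } else {
      x <- dplyr::distinct(x, .data$marker, .keep_all = TRUE)
    }
    x <- dplyr::count(x, .data$category, name = "count")
  }
  pr <- 100 * x$count / denominator
  dplyr::mutate(x[, c("category", "count")],
                percent = round_half_up(pr, 2), percent_raw = pr)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate discovery, filter,
#' design the array, simulate and QC family genotypes, assign parentage,
#' estimate the maps, and summarise — writing each stage's output as
#' stand-alone TSV/VCF files under `out_dir` together with a JSON echo of
#' the configuration and seed. Stage toggles skip later stages.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param stages Character vector of stages to run, a prefix of
#'   `c("simulate", "filter", "design", "qc", "parentage", "map",
#'   "report")`.
#' @param filter_cfg,design_cfg,qc_thr Stage configurations.
#' @param write_vcf_files Write discovery/kept VCFs (default FALSE; they are
#'   the largest outputs).
#' @return A run report list with per-stage input/output counts and the
#'   stage results themselves.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         stages = c("simulate", "filter", "design", "qc",
                                    "parentage", "map", "report"),
                         filter_cfg = filter_config(),
                         design_cfg = array_design_config(),
                         qc_thr = qc_thresholds(),
                         write_vcf_files = FALSE) {
  all_stages <- c("simulate", "filter", "design", "qc", "parentage", "map",
                  "report")
  stages <- all_stages[all_stages %in% stages]
  assert_that(length(stages) > 0, "no stages selected")
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_table(x, file.path(out_dir, name))
    invisible(x)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_echo <- config
    cfg_echo$true_maps <- lapply(cfg_echo$true_maps, lapply, as.data.frame)
    jsonlite::write_json(unclass(cfg_echo), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report <- list(seed = config$seed, stages = list())
  tick <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }

  disc <- simulate_discovery_cohort(config)
  tick("simulate", n_records = nrow(disc$variants$sites),
       n_founders = length(disc$variants$samples))
  if (!is.null(out_dir) && write_vcf_files) {
    write_vcf(disc$variants, file.path(out_dir, "discovery.vcf"))
  }
  out <- list(discovery = disc)
  if (!"filter" %in% stages) return(c(out, list(report = report)))

  fr <- filter_discovery_variants(disc$variants, filter_cfg)
  emit(dplyr::mutate(fr$removed), "filter_removed.tsv")
  emit(fr$stats, "filter_stats.tsv")
  tick("filter", n_in = nrow(fr$stats), n_kept = length(fr$kept))
  out$filter <- fr
  if (!"design" %in% stages) return(c(out, list(report = report)))

  cand <- tidy(fr)[tidy(fr)$kept, c("marker", "chrom", "pos", "maf")]
  sel <- select_array(cand, annotations = NULL, layout = config$genome,
                      config = design_cfg)
  emit(sel$chosen, "design.tsv")
  tick("design", n_candidates = nrow(cand), n_chosen = nrow(sel$chosen))
  out$design <- sel
  if (!"qc" %in% stages) return(c(out, list(report = report)))

  panel <- dplyr::left_join(sel$chosen[, c("marker", "chrom", "pos")],
                            disc$truth$sites[, c("id", "freq")],
                            by = c(marker = "id"))
  # families are genotyped at the linkage-group content of the array
  panel <- panel[panel$chrom %in% names(config$true_maps), , drop = FALSE]
  fam <- simulate_families(config, markers = panel)
  if (!is.null(out_dir)) {
    write_genotypes_tsv(fam$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_table(fam$sex[, c("id", "sex")], file.path(out_dir, "sexes.tsv"))
  }
  qc <- qc_summary(fam$genotypes, qc_thr)
  emit(qc$snp, "qc_snps.tsv")
  emit(qc$samples, "qc_samples.tsv")
  tick("qc", n_markers = nrow(qc$snp),
       n_mapping_ready = sum(qc$snp$mapping_ready))
  out$families <- fam
  out$qc <- qc
  if (!"parentage" %in% stages) return(c(out, list(report = report)))

  parents <- fam$pedigree$id[is.na(fam$pedigree$sire)]
  kids <- setdiff(fam$genotypes$samples, parents)
  asg <- assign_parents(fam$genotypes, kids, parents,
                        sexes = fam$sex)
  fams <- build_families(asg)
  emit(asg$assignments, "assignments.tsv")
  ped_out <- asg$assignments[, c("id", "sire", "dam")]
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  ped_out$sex <- fam$sex$sex[match(ped_out$id, fam$sex$id)]
  emit(ped_out, "pedigree.tsv")
  tick("parentage", n_offspring = length(kids),
       n_resolved = sum(asg$assignments$resolved),
       n_families = fams$stats$n_families)
  out$parentage <- asg
  out$family_table <- fams
  if (!"map" %in% stages) return(c(out, list(report = report)))

  keep_mk <- qc$snp$marker[qc$snp$mapping_ready & qc$snp$maf > 0.05]
  gm2 <- subset_markers(fam$genotypes, keep_mk)
  ped <- asg$assignments[asg$assignments$resolved, c("id", "sire", "dam")]
  map <- estimate_map(gm2, ped)
  emit(map$positions, "map.tsv")
  sexres <- map_sex_locus(gm2, ped, map, fam$sex)
  tick("map", n_markers = nrow(map$positions),
       sex_locus = if (sexres$status == "ok")
         paste0(sexres$lg, ":", sexres$peak_bp) else "unresolved")
  out$map <- map
  out$sex_locus <- sexres
  if (!"report" %in% stages) return(c(out, list(report = report)))

  summ <- map_summary(map, layout = config$genome)
  emit(summ, "map_summary.tsv")
  counts <- dplyr::count(disc$variants$sites, .data$chrom, name = "variants")
  names(counts)[1] <- "name"
  dens <- density_summary(config$genome, counts)
  emit(dens, "density_summary.tsv")
  tick("report", tables = c("map_summary", "density_summary"))
  out$map_summary <- summ
  out$density <- dens
  out$report <- report
  out
}

#' Restrict a genotype matrix to a marker subset
#'
#' @param gm A [genotype_matrix()].
#' @param markers Character vector of marker ids to keep.
#' @return A [genotype_matrix()].
#' @export
subset_markers <- function(gm, markers) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- gm$markers$marker %in% markers
  genotype_matrix(gm$codes[, keep, drop = FALSE],
                  gm$markers[keep, , drop = FALSE], gm$samples)
}
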