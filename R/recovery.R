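# A packaged parameter-recovery study: run the whole pipeline on synthetic
# data with known truth and measure how well each stage recovers it.

#' Parameter-recovery study at study scale
#'
#' Runs discovery simulation, the filtering cascade, array design, family
#' simulation, parentage assignment, map estimation, sex-locus mapping and
#' desert detection on the default three-LG genome with 40 full-sib
#' families of 16 offspring, and compares every estimate against the
#' generator's truth. Maps and the sex locus are estimated from the
#' array-designed marker panel; parentage runs on the full filtered panel
#' (mirroring the published 43k-SNP parentage condition). Both simulator
#' and estimator use Haldane distances here so the crossover process and
#' the mapping function agree exactly.
#'
#' @param seed Integer seed driving every stage.
#' @param error_rate Genotyping error rate for the mapping families
#'   (default 0.002).
#' @param parentage_error_rate Error rate for the noisy parentage
#'   experiment (default 0.005).
#' @param n_families,offspring_per_family Family structure
#'   (defaults 40 x 16).
#' @return A list of recovery metrics: per-LG map-length errors on each
#'   track, total-length errors per sex, the recovered F:M ratio, sex-locus
#'   error in cM (sex-averaged), terminal-desert coverage, and parentage
#'   accuracy at zero and at `parentage_error_rate` noise.
#' @export
recovery_study <- function(seed, error_rate = 0.002,
                           parentage_error_rate = 0.005,
                           n_families = 40, offspring_per_family = 16L) {
  cfg <- sim_config(seed = seed, n_families = n_families,
                    offspring_per_family = offspring_per_family,
                    error_rate = error_rate)
  disc <- simulate_discovery_cohort(cfg)
  fr <- filter_discovery_variants(disc$variants)
  cand <- tidy(fr)
  cand <- cand[cand$kept, c("marker", "chrom", "pos", "maf")]
  sel <- select_array(cand, layout = cfg$genome)
  freqs <- disc$truth$sites$freq[match(sel$chosen$marker, disc$truth$sites$id)]
  lg_names <- names(cfg$true_maps)
  array_panel <- dplyr::mutate(sel$chosen[, c("marker", "chrom", "pos")],
                               freq = freqs)
  array_panel <- array_panel[array_panel$chrom %in% lg_names, , drop = FALSE]

  fam <- simulate_families(cfg, markers = array_panel)
  ped <- fam$pedigree[!is.na(fam$pedigree$sire), , drop = FALSE]
  qc <- qc_summary(fam$genotypes)
  keep <- qc$snp$marker[qc$snp$mapping_ready & !is.na(qc$snp$maf) &
                          qc$snp$maf > 0.05]
  gm <- subset_markers(fam$genotypes, keep)
  map <- estimate_map(gm, ped, mapping_fun = "haldane")
  summ <- map_summary(map, layout = cfg$genome)

  truth_f <- vapply(cfg$true_maps, function(x) max(x$female$cm), numeric(1))
  truth_m <- vapply(cfg$true_maps, function(x) max(x$male$cm), numeric(1))
  truth_sa <- (truth_f + truth_m) / 2  # pooled meioses, equal counts per sex
  ord <- match(summ$lg, names(truth_f))
  err <- function(est, tru) 100 * (est / tru - 1)
  per_lg <- tibble(
    lg = summ$lg,
    err_female_pct = err(summ$female_cm, truth_f[ord]),
    err_male_pct = err(summ$male_cm, truth_m[ord]),
    err_sexavg_pct = err(summ$sexavg_cm, truth_sa[ord]))

  sl <- map_sex_locus(gm, ped, map, fam$sex)
  sl_err_cm <- NA_real_
  if (sl$status == "ok" && sl$lg == cfg$sex_locus$chrom) {
    pos_lg <- map$positions[map$positions$lg == cfg$sex_locus$chrom, ]
    truth_cm <- stats::approx(pos_lg$bp, pos_lg$cm_sexavg,
                              xout = cfg$sex_locus$pos, rule = 2)$y
    sl_err_cm <- abs(sl$peak_cm_sexavg - truth_cm)
  }

  des <- detect_deserts(map)
  desert_cov <- vapply(lg_names, function(lg) {
    d <- des[des$lg == lg & des$terminal & des$start_bp < 1e6, , drop = FALSE]
    if (nrow(d) == 0) return(0)
    max(pmin(d$end_bp, cfg$desert_bp) - pmax(d$start_bp, 0)) / cfg$desert_bp
  }, numeric(1))

  parentage_acc <- function(eps, miss) {
    cfg_p <- sim_config(seed = seed, n_families = n_families,
                        offspring_per_family = offspring_per_family,
                        error_rate = eps, missing_rate = miss)
    full_panel <- cand[cand$chrom %in% lg_names, c("marker", "chrom", "pos")]
    full_panel$freq <- disc$truth$sites$freq[match(full_panel$marker,
                                                   disc$truth$sites$id)]
    famp <- simulate_families(cfg_p, markers = full_panel)
    pedp <- famp$pedigree[!is.na(famp$pedigree$sire), , drop = FALSE]
    parents <- famp$pedigree$id[is.na(famp$pedigree$sire)]
    asg <- assign_parents(famp$genotypes, pedp$id, parents, sexes = famp$sex)
    tbl <- asg$assignments
    mean(tbl$resolved &
           tbl$sire == pedp$sire[match(tbl$id, pedp$id)] &
           tbl$dam == pedp$dam[match(tbl$id, pedp$id)])
  }

  list(
    config = cfg,
    n_panel_markers = nrow(array_panel),
    n_map_markers = nrow(gm$markers),
    per_lg = per_lg,
    map_summary = summ,
    err_total_female_pct = err(sum(summ$female_cm), sum(truth_f)),
    err_total_male_pct = err(sum(summ$male_cm), sum(truth_m)),
    fm_ratio = sum(summ$female_cm) / sum(summ$male_cm),
    sex_locus = sl,
    sex_locus_err_cm = sl_err_cm,
    desert_coverage = desert_cov,
    parentage_acc_clean = parentage_acc(0, 0),
    parentage_acc_noisy = parentage_acc(parentage_error_rate, 0.01)
  )
}
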