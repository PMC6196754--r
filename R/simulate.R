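# Synthetic-data generator: founder discovery cohorts and factorial full-sib
# families with sex-differentiated recombination, an XY sex locus, and
# genotyping noise. Every draw flows from config$seed, so outputs are
# reproducible byte-for-byte.

#' Simulate a discovery (resequencing) founder cohort
#'
#' Places candidate variant sites along the configured genome as a Poisson
#' process, draws founder genotypes in Hardy-Weinberg proportions at each
#' site, and emits a [variant_table()] with per-sample depth and genotype
#' quality plus site quality, including the record types the discovery filter
#' has to handle: INDEL and MNP records, A/T and C/G SNPs, multi-allelic
#' SNPs, low-QUAL and low-GQ draws.
#'
#' @param config A [sim_config()].
#' @return A list with elements `variants` (a [variant_table()]) and `truth`
#'   (site tibble with true allele frequencies, plus the pre-noise genotype
#'   matrix).
#' @examples
#' sim <- simulate_discovery_cohort(sim_config(
#'   genome = genome_layout("LG01", 2e5), seed = 7))
#' sim$variants
#' @export
simulate_discovery_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$genome
  sites <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    n <- rpois(1, g$length_bp[i] / config$site_density_bp)
    if (n == 0) return(NULL)
    pos <- sort(unique(ceiling(runif(n, 1, g$length_bp[i] - 1))))
    tibble(chrom = g$name[i], pos = pos)
  })
  if (is.null(sites) || nrow(sites) == 0) {
    abort_onilmap("no candidate sites drawn for this genome/density",
                  "onilmap_config_error")
  }
  m <- nrow(sites)
  n <- config$n_founders
  sites$id <- sprintf("SNP_%s_%d", sites$chrom, sites$pos)
  sites$freq <- runif(m, config$maf_range[1], config$maf_range[2])

  # Record type mix.
  u <- runif(m)
  type <- ifelse(u < config$indel_frac, "INDEL",
                 ifelse(u < config$indel_frac + config$mnp_frac, "MNP", "SNP"))
  is_snp <- type == "SNP"
  u2 <- runif(m)
  atcg <- is_snp & u2 < config$atcg_frac
  multi <- is_snp & !atcg &
    u2 < config$atcg_frac + config$multiallelic_frac

  alleles <- draw_alleles(type, atcg, multi)
  qual <- ifelse(runif(m) < config$qual_below20_frac,
                 runif(m, 1, 20), runif(m, 20.5, 3000))

  # Hardy-Weinberg genotypes: alt-allele dosage ~ Binomial(2, freq).
  gt <- matrix(rbinom(m * n, 2, rep(sites$freq, n)), m, n)
  storage.mode(gt) <- "integer"
  dp <- matrix(rpois(m * n, config$depth_mean), m, n)
  low <- runif(m * n) < config$gq_below30_frac
  gq <- matrix(ifelse(low, floor(runif(m * n, 5, 30)),
                      floor(runif(m * n, 30, 100))), m, n)
  samples <- sprintf("founder_%02d", seq_len(n))
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples

  vt <- variant_table(
    tibble(chrom = sites$chrom, pos = sites$pos, id = sites$id,
           ref = alleles$ref, alt = alleles$alt, qual = round(qual, 1)),
    gt = gt, dp = dp, gq = gq, samples = samples)
  truth <- list(
    sites = dplyr::mutate(sites, type = type),
    genotypes = gt,
    config = config
  )
  list(variants = vt, truth = truth)
}

draw_alleles <- function(type, atcg, multi) {
  m <- length(type)
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4, m, replace = TRUE)]
  # A/T and C/G pairs need twice the probes on the array; their fraction is
  # controlled exactly, so ordinary draws avoid those pairs.
  allowed <- list(A = c("C", "G"), C = c("A", "T"),
                  G = c("A", "T"), T = c("C", "G"))
  alt <- vapply(ref, function(r) sample(allowed[[r]], 1), character(1))
  pair_at <- runif(m) < 0.5
  ref[atcg] <- ifelse(pair_at[atcg], "A", "C")
  alt[atcg] <- ifelse(pair_at[atcg], "T", "G")
  if (any(multi)) {
    alt[multi] <- vapply(which(multi), function(i) {
      paste(sample(setdiff(bases, ref[i]), 2), collapse = ",")
    }, character(1))
  }
  ins <- runif(m) < 0.5
  idx <- which(type == "INDEL")
  for (i in idx) {
    if (ins[i]) alt[i] <- paste0(ref[i], sample(bases, 1))
    else { ref[i] <- paste0(ref[i], sample(bases, 1)); alt[i] <- substr(ref[i], 1, 1) }
  }
  idx <- which(type == "MNP")
  for (i in idx) {
    r2 <- sample(bases, 1); a2 <- sample(setdiff(bases, r2), 1)
    alt[i] <- paste0(alt[i], a2); ref[i] <- paste0(ref[i], r2)
  }
  list(ref = unname(ref), alt = unname(alt))
}

#' Simulate genotyped factorial full-sib families
#'
#' Draws a factorial parent pool in Hardy-Weinberg proportions at the marker
#' panel, transmits gametes by an interference-free crossover process
#' (crossover count per meiosis ~ Poisson of the transmitting parent's
#' sex-specific map length in Morgans; positions uniform in cM, placed in bp
#' by inverse Marey interpolation), determines each offspring's sex from the
#' sire-transmitted allele at the XY locus, then applies the genotyping noise
#' model (symmetric flips to a different code with probability `error_rate`,
#' missing with probability `missing_rate`) to offspring genotypes
#' (post-transmission; `noise_scope = "all"` also noises parents).
#'
#' @param config A [sim_config()].
#' @param founders Optional result of [simulate_discovery_cohort()]; when
#'   given, the family marker panel defaults to its SNP sites on assigned
#'   linkage groups with their true allele frequencies.
#' @param markers Optional marker panel tibble (`marker`, `chrom`, `pos`, and
#'   optionally `freq`); overrides `founders`. Without `freq`, frequencies
#'   are drawn from the configured founder law.
#' @return A list with `genotypes` (a [genotype_matrix()] of parents +
#'   offspring), `sex` (tibble `id`, `sex` with 12 = male / 11 = female
#'   codes and an `MF` column), `pedigree` (tibble `id`, `sire`, `dam`,
#'   `sex`), and `truth` (parent haplotypes, per-meiosis crossovers, true
#'   maps, true sex-locus position, pre-noise genotypes).
#' @export
simulate_families <- function(config, founders = NULL, markers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lg_names <- names(config$true_maps)
  if (is.null(markers)) {
    if (!is.null(founders)) {
      tr <- founders$truth$sites
      keep <- tr$type == "SNP" & tr$chrom %in% lg_names
      markers <- tibble(marker = tr$id[keep], chrom = tr$chrom[keep],
                        pos = tr$pos[keep], freq = tr$freq[keep])
    } else {
      # stand-alone panel drawn from the configured lattice + frequency law
      g <- config$genome[config$genome$name %in% lg_names, , drop = FALSE]
      markers <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
        n <- rpois(1, g$length_bp[i] / config$site_density_bp)
        pos <- sort(unique(ceiling(runif(n, 1, g$length_bp[i] - 1))))
        tibble(marker = sprintf("SNP_%s_%d", g$name[i], pos),
               chrom = g$name[i], pos = pos)
      })
    }
  }
  markers <- as_tibble(markers)
  if (!"freq" %in% names(markers)) {
    markers$freq <- runif(nrow(markers), config$maf_range[1], config$maf_range[2])
  }
  markers <- dplyr::arrange(markers, .data$chrom, .data$pos)
  assert_that(nrow(markers) > 0, "empty marker panel", "onilmap_config_error")
  assert_that(all(markers$chrom %in% lg_names),
              "family markers must lie on assigned linkage groups",
              "onilmap_config_error")
  sl <- config$sex_locus
  assert_that(sl$chrom %in% lg_names, "sex locus outside mapped genome",
              "onilmap_config_error")

  n_s <- config$n_sires; n_d <- config$n_dams
  sires <- sprintf("sire_%02d", seq_len(n_s))
  dams <- sprintf("dam_%02d", seq_len(n_d))
  m <- nrow(markers)

  # Parent haplotypes in linkage equilibrium at the panel frequencies.
  hap <- function() matrix(rbinom(2L * m, 1, rep(markers$freq, each = 2)),
                           nrow = 2L)
  par_haps <- c(lapply(sires, function(.) hap()), lapply(dams, function(.) hap()))
  names(par_haps) <- c(sires, dams)

  # Distinct factorial (sire, dam) pairs.
  grid <- expand.grid(sire = sires, dam = dams, stringsAsFactors = FALSE)
  assert_that(config$n_families <= nrow(grid),
              "more families than distinct parent pairs", "onilmap_config_error")
  fam <- grid[sample.int(nrow(grid), config$n_families), , drop = FALSE]
  opf <- config$offspring_per_family
  sizes <- if (length(opf) > 1) {
    rep_len(as.integer(opf), config$n_families)
  } else if (opf %% 1 == 0) {
    rep(as.integer(opf), config$n_families)
  } else {
    # fractional mean -> Poisson family sizes, floored at the minimum size
    pmax(config$min_family, rpois(config$n_families, opf))
  }

  by_lg <- split(seq_len(m), markers$chrom)[unique(markers$chrom)]
  lg_of_sex <- sl$chrom
  n_off <- sum(sizes)
  off_ids <- sprintf("off_%04d", seq_len(n_off))

  geno_off <- matrix(0L, n_off, m)
  sex_off <- logical(n_off)  # TRUE = male
  crossovers <- vector("list", 0)
  transmitted <- list()
  ped <- tibble(id = off_ids, sire = rep(fam$sire, sizes),
                dam = rep(fam$dam, sizes), sex = NA_character_)

  meiosis <- function(parent_hap, lg, idx, female, y_hap = NA) {
    curve <- config$true_maps[[lg]][[if (female) "female" else "male"]]
    total_cm <- max(curve$cm)
    n_co <- rpois(1, total_cm / 100)
    co_bp <- if (n_co > 0) sort(marey_bp_at(curve, runif(n_co, 0, total_cm))) else numeric(0)
    h0 <- sample(0:1, 1)
    which_hap <- (h0 + findInterval(markers$pos[idx], co_bp)) %% 2L
    allele <- parent_hap[cbind(which_hap + 1L, idx)]
    sexed <- NA
    if (!female && lg == lg_of_sex) {
      hap_at_sex <- (h0 + findInterval(sl$pos, co_bp)) %% 2L
      sexed <- hap_at_sex == 1L  # haplotype 2 of every sire carries Y
    }
    list(allele = allele, co = co_bp, h0 = h0, male = sexed)
  }

  row <- 0L
  co_log <- vector("list", n_off)
  for (f in seq_len(nrow(fam))) {
    sh <- par_haps[[fam$sire[f]]]
    dh <- par_haps[[fam$dam[f]]]
    for (k in seq_len(sizes[f])) {
      row <- row + 1L
      co_this <- list()
      for (lg in names(by_lg)) {
        idx <- by_lg[[lg]]
        pat <- meiosis(sh, lg, idx, female = FALSE)
        mat <- meiosis(dh, lg, idx, female = TRUE)
        geno_off[row, idx] <- pat$allele + mat$allele
        if (!is.na(pat$male)) sex_off[row] <- pat$male
        co_this[[lg]] <- list(paternal = pat$co, maternal = mat$co,
                              paternal_h0 = pat$h0, maternal_h0 = mat$h0)
      }
      co_log[[row]] <- co_this
    }
  }

  # Parent genotype rows (pre-noise = haplotype sums).
  geno_par <- t(vapply(par_haps, function(h) as.integer(colSums(h)), integer(m)))
  all_ids <- c(sires, dams, off_ids)
  codes_true <- rbind(geno_par, geno_off)
  dimnames(codes_true) <- list(all_ids, markers$marker)

  codes <- codes_true
  noise_rows <- if (config$noise_scope == "all") seq_len(nrow(codes)) else
    (n_s + n_d) + seq_len(n_off)
  if (config$error_rate > 0 && length(noise_rows)) {
    blk <- codes[noise_rows, , drop = FALSE]
    flip <- runif(length(blk)) < config$error_rate
    shift <- sample(1:2, sum(flip), replace = TRUE)
    blk[flip] <- (blk[flip] + shift) %% 3L
    codes[noise_rows, ] <- blk
  }
  if (config$missing_rate > 0 && length(noise_rows)) {
    blk <- codes[noise_rows, , drop = FALSE]
    blk[runif(length(blk)) < config$missing_rate] <- -1L
    codes[noise_rows, ] <- blk
  }

  gm <- genotype_matrix(codes,
                        markers = markers[, c("marker", "chrom", "pos")],
                        samples = all_ids)
  sex_chr <- ifelse(sex_off, "M", "F")
  ped$sex <- sex_chr
  sex_tbl <- tibble(
    id = all_ids,
    MF = c(rep("M", n_s), rep("F", n_d), sex_chr),
    sex = ifelse(c(rep("M", n_s), rep("F", n_d), sex_chr) == "M", "12", "11"))
  pedigree <- dplyr::bind_rows(
    tibble(id = c(sires, dams), sire = NA_character_, dam = NA_character_,
           sex = c(rep("M", n_s), rep("F", n_d))),
    ped)

  list(
    genotypes = gm,
    sex = sex_tbl,
    pedigree = pedigree,
    families = tibble(sire = fam$sire, dam = fam$dam, size = sizes),
    truth = list(
      parent_haplotypes = par_haps,
      crossovers = stats::setNames(co_log, off_ids),
      genotypes_pre_noise = codes_true,
      markers = markers,
      true_maps = config$true_maps,
      sex_locus = sl,
      config = config
    )
  )
}
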