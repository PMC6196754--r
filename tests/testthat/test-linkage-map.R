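# Map functions, transmission resolution, phasing, map estimation, deserts
# and sex-locus mapping.

test_that("Kosambi and Haldane functions match their closed forms and invert", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  r <- seq(0, 0.49, by = 0.005)
  expect_lt(max(abs(kosambi_inv(kosambi_cm(r)) - r)), 1e-12)
  expect_lt(max(abs(haldane_inv(haldane_cm(r)) - r)), 1e-12)
  expect_error(kosambi_cm(0.5), "0.5")
})

test_that("transmission resolution handles forced, ambiguous and impossible trios", {
  mk <- tibble::tibble(marker = paste0("m", 1:3), chrom = "LG01", pos = 1:3)
  # markers: (sire het, dam hom-ref), (both het), (sire het, dam hom-ref)
  codes <- rbind(sire = c(1L, 1L, 1L),
                 dam = c(0L, 1L, 0L),
                 off = c(1L, 1L, 2L))
  gm <- genotype_matrix(codes, mk, samples = c("sire", "dam", "off"))
  rt <- resolve_transmissions(gm, "sire", "dam", "off")
  expect_equal(unname(rt$sire[1, 1]), 1L)      # dam gave ref, offspring het: alt from sire
  expect_true(is.na(rt$sire[1, 2]))            # both het + het offspring: unknown
  expect_true(is.na(rt$sire[1, 3]))            # offspring 2 with dam 0: impossible
  expect_equal(rt$mendel_flagged, "m3")
})

test_that("phase_parent equals exhaustive 2^M minimisation", {
  set.seed(31)
  for (rep in 1:30) {
    m <- sample(2:12, 1)
    n <- sample(2:8, 1)
    A <- matrix(sample(c(0L, 1L, NA), n * m, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), n, m)
    expect_equal(phase_parent(A)$crossovers, phase_oracle(A))
  }
})

test_that("phase absorbs global flips and masking removes isolated errors", {
  # four offspring, identical indicators after one global flip: 0 crossovers
  A <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L),
             c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  expect_equal(phase_parent(A)$crossovers, 0)

  # one isolated flip flanked by agreement: 2 crossovers raw, 0 after masking
  A2 <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L),
              c(0L, 0L, 1L, 0L, 0L, 0L))
  ph <- phase_parent(A2)
  expect_equal(ph$crossovers, 2)
  H <- onilmap:::mask_isolated_flips(ph$hap)
  v <- H[2, !is.na(H[2, ])]
  expect_equal(sum(v[-1] != v[-length(v)]), 0)
})

test_that("single-marker and empty phasing inputs degrade gracefully", {
  one <- matrix(c(0L, 1L, NA), 3, 1)
  expect_equal(phase_parent(one)$crossovers, 0)
  zero <- matrix(integer(), 3, 0)
  expect_equal(phase_parent(zero)$crossovers, 0)
})

test_that("map length recovers truth and is invariant to order reversal", {
  fx <- map_fixture(seed = 61, error_rate = 0, missing_rate = 0,
                    length_bp = 30e6, site_density_bp = 40000,
                    n_families = 16, offspring = 16L)
  gm <- fx$fam$genotypes
  map <- estimate_map(gm, fx$ped, mapping_fun = "haldane")
  g <- glance(map)
  truth_f <- max(fx$cfg$true_maps$LG01$female$cm)
  truth_m <- max(fx$cfg$true_maps$LG01$male$cm)
  expect_lt(abs(g$female_cm - truth_f) / truth_f, 0.2)
  expect_lt(abs(g$male_cm - truth_m) / truth_m, 0.2)

  # reversal: flip coordinates, lengths must be identical
  mk2 <- gm$markers
  mk2$pos <- 30e6 + 1 - mk2$pos
  gm2 <- genotype_matrix(gm$codes, mk2, gm$samples)
  g2 <- glance(estimate_map(gm2, fx$ped, mapping_fun = "haldane"))
  expect_equal(g2$female_cm, g$female_cm, tolerance = 1e-9)
  expect_equal(g2$male_cm, g$male_cm, tolerance = 1e-9)
})

test_that("phased crossover counts track the simulated truth", {
  fx <- map_fixture(seed = 67, error_rate = 0, missing_rate = 0,
                    length_bp = 20e6, site_density_bp = 30000,
                    n_families = 8, offspring = 16L)
  gm <- fx$fam$genotypes
  ped <- fx$ped
  lgidx <- which(gm$markers$chrom == "LG01")
  total_est <- 0; total_true <- 0
  for (p in unique(ped$sire)) {
    res <- onilmap:::resolve_for_parent(gm, ped, p, "sire")
    A <- res$ind[, intersect(lgidx, res$het), drop = FALSE]
    total_est <- total_est + phase_parent(A)$crossovers
    total_true <- total_true + sum(vapply(res$offspring, function(o) {
      length(fx$fam$truth$crossovers[[o]]$LG01$paternal)
    }, numeric(1)))
  }
  # min-recombination undercounts only crossovers invisible to the marker set
  # detection requires both flanking markers resolved (~65% of crossovers)
  expect_lte(total_est, total_true)
  expect_gt(total_est, 0.5 * total_true)
})

test_that("deserts: uniform maps have none, zero maps are one whole-LG desert", {
  mkmap <- function(cm) {
    structure(list(
      positions = tibble::tibble(lg = "LG01", marker = paste0("m", 1:11),
                                 bp = seq(0, 10e6, by = 1e6),
                                 cm_female = cm, cm_male = cm, cm_sexavg = cm),
      intervals = NULL, mapping_fun = "kosambi"), class = "genetic_map")
  }
  uniform <- mkmap(seq(0, 10, by = 1))       # 1 cM/Mb everywhere
  expect_equal(nrow(detect_deserts(uniform)), 0)
  flat <- mkmap(rep(0, 11))                  # whole-LG desert, terminal
  d <- detect_deserts(flat)
  expect_equal(nrow(d), 1)
  expect_equal(d$span_bp, 10e6)
  expect_true(d$terminal)
})

test_that("map_summary reproduces published-style ratios and densities", {
  per <- map_summary(
    structure(list(positions = tibble::tibble(
      lg = "LG01", marker = c("a", "b", "c"),
      bp = c(0, 19e6, 38.37e6),
      cm_female = c(0, 36, 71.64), cm_male = c(0, 27, 53.35),
      cm_sexavg = c(0, 31, 62.11)),
      intervals = NULL, mapping_fun = "kosambi"), class = "genetic_map"),
    layout = genome_layout("LG01", 38.37e6))
  expect_equal(per$fm_ratio, 1.34)
  expect_equal(per$female_cm, 71.64)
  # a strictly linear Marey relation has correlation 1
  lin <- map_summary(
    structure(list(positions = tibble::tibble(
      lg = "LG01", marker = paste0("m", 1:5), bp = 1:5 * 1e6,
      cm_female = 1:5, cm_male = 1:5 * 2, cm_sexavg = 1:5 * 1.5),
      intervals = NULL, mapping_fun = "kosambi"), class = "genetic_map"))
  expect_equal(lin$cor_female, 1)
  expect_equal(lin$cor_male, 1)
})

test_that("zero male length yields an undefined ratio, not an error", {
  per <- map_summary(
    structure(list(positions = tibble::tibble(
      lg = "LG01", marker = c("a", "b"), bp = c(0, 1e6),
      cm_female = c(0, 10), cm_male = c(0, 0), cm_sexavg = c(0, 5)),
      intervals = NULL, mapping_fun = "kosambi"), class = "genetic_map"))
  expect_true(is.na(per$fm_ratio))
})

test_that("sex-locus mapping needs two sexes and flags the unresolvable case", {
  fx <- map_fixture(seed = 71, length_bp = 4e6, site_density_bp = 20000,
                    n_families = 3, offspring = 8L)
  map <- estimate_map(fx$fam$genotypes, fx$ped)
  all_male <- fx$fam$sex
  all_male$sex <- "12"
  res <- map_sex_locus(fx$fam$genotypes, fx$ped, map, all_male)
  expect_equal(res$status, "unresolvable")
  expect_equal(nrow(tidy(res)), 0)
})

test_that("estimate_map requires usable trios", {
  fx <- map_fixture(seed = 72, length_bp = 1e6, site_density_bp = 50000,
                    n_families = 2, offspring = 8L)
  bad_ped <- tibble::tibble(id = "nobody", sire = "ghost", dam = "ghost2")
  expect_error(estimate_map(fx$fam$genotypes, bad_ped),
               class = "onilmap_precondition")
})
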