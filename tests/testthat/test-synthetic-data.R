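# The synthetic-data generator: reproducibility, distributional structure,
# Mendelian transmission, sex determination, and the study-scale defaults.

test_that("the generator is reproducible bit-for-bit under a seed", {
  a <- simulate_discovery_cohort(tiny_config(seed = 7))
  b <- simulate_discovery_cohort(tiny_config(seed = 7))
  expect_identical(a$variants$gt, b$variants$gt)
  expect_identical(a$variants$sites, b$variants$sites)
  expect_identical(a$variants$gq, b$variants$gq)
  c <- simulate_discovery_cohort(tiny_config(seed = 8))
  expect_false(identical(a$variants$gt, c$variants$gt))

  fa <- simulate_families(tiny_config(seed = 7))
  fb <- simulate_families(tiny_config(seed = 7))
  expect_identical(fa$genotypes$codes, fb$genotypes$codes)
  expect_identical(fa$sex, fb$sex)
})

test_that("founder genotypes follow Hardy-Weinberg at the configured frequency", {
  # allele frequency pinned at 0.5: expected het fraction 2pq = 0.5
  cfg <- tiny_config(seed = 21, maf_range = c(0.5, 0.5), n_founders = 32,
                     indel_frac = 0, mnp_frac = 0, atcg_frac = 0,
                     multiallelic_frac = 0)
  sim <- simulate_discovery_cohort(cfg)
  gt <- sim$variants$gt
  het <- mean(gt == 1L)
  n <- length(gt)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se + 1e-9)
})

test_that("record-type fractions follow their binomial laws", {
  cfg <- sim_config(genome = genome_layout("LG01", 2.2e6), seed = 5,
                    indel_frac = 0.1)
  sim <- simulate_discovery_cohort(cfg)
  cls <- sim$variants$sites$variant_class
  n <- length(cls)
  expect_gt(n, 800)
  k <- sum(cls == "INDEL")
  se <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(k - 0.1 * n), 4 * se)
})

test_that("transmission is Mendelian with zero noise and traceable to haplotypes", {
  fx <- map_fixture(seed = 31, length_bp = 2e6, site_density_bp = 8000,
                    n_families = 3, offspring = 8L)
  gm <- fx$fam$genotypes
  ped <- fx$ped
  for (f in seq_len(nrow(fx$fam$families))) {
    fam_row <- fx$fam$families[f, ]
    kids <- ped$id[ped$sire == fam_row$sire & ped$dam == fam_row$dam]
    rt <- resolve_transmissions(gm, fam_row$sire, fam_row$dam, kids)
    expect_length(rt$mendel_flagged, 0)
  }
  # every offspring genotype equals the sum of two parental haplotype alleles
  truth <- fx$fam$truth
  off <- setdiff(gm$samples, fx$fam$pedigree$id[is.na(fx$fam$pedigree$sire)])
  expect_identical(gm$codes[off, ], truth$genotypes_pre_noise[off, ])
})

test_that("a zero-length male map transmits one intact paternal haplotype", {
  cfg <- sim_config(genome = genome_layout("LG01", 1e6), seed = 13,
                    male_cm_per_mb = 0, fm_ratio = 1e6, # female map kept finite
                    n_families = 2, offspring_per_family = 6L,
                    n_sires = 2, n_dams = 2,
                    error_rate = 0, missing_rate = 0, site_density_bp = 20000)
  # fm_ratio misuse guard: build female length directly instead
  cfg$true_maps$LG01$female <- marey_curve(1e6, 2, desert_bp = 0)
  fam <- simulate_families(cfg)
  for (o in names(fam$truth$crossovers)) {
    expect_length(fam$truth$crossovers[[o]]$LG01$paternal, 0)
  }
})

test_that("offspring sex is genetic: XY sire transmissions determine sex", {
  fx <- map_fixture(seed = 41, length_bp = 3e6, site_density_bp = 10000,
                    n_families = 4, offspring = 10L)
  fam <- fx$fam
  sl <- fx$cfg$sex_locus
  for (o in fam$pedigree$id[!is.na(fam$pedigree$sire)]) {
    co <- fam$truth$crossovers[[o]][[sl$chrom]]
    hap_at_sex <- (co$paternal_h0 + findInterval(sl$pos, co$paternal)) %% 2
    expect_equal(fam$pedigree$sex[fam$pedigree$id == o],
                 ifelse(hap_at_sex == 1, "M", "F"))
  }
  # both sexes occur and are roughly balanced
  tab <- table(fam$pedigree$sex[!is.na(fam$pedigree$sire)])
  expect_true(all(c("M", "F") %in% names(tab)))
})

test_that("study-scale defaults give ~41 families totalling ~689 offspring", {
  cfg <- sim_config(seed = 99, site_density_bp = 5e5)  # sparse markers: fast
  fam <- simulate_families(cfg)
  expect_equal(nrow(fam$families), 41)
  expect_true(all(fam$families$size >= 8))
  total <- sum(fam$families$size)
  # Poisson(16.81) x 41: sd ~ 26, so a generous window around 689
  expect_gt(total, 600)
  expect_lt(total, 780)
})

test_that("realized recombinant fraction matches map distance for close markers", {
  # two markers 0.5 cM apart, 10,000 meioses: r ~ d/100 within 3 SE
  cfg <- sim_config(genome = genome_layout("LG01", 1e6), seed = 55,
                    n_families = 1, offspring_per_family = 10000L,
                    n_sires = 1, n_dams = 1, error_rate = 0, missing_rate = 0,
                    site_density_bp = 5e5)
  cfg$true_maps$LG01$male <- tibble::tibble(bp = c(0, 1e6), cm = c(0, 1))
  cfg$true_maps$LG01$female <- tibble::tibble(bp = c(0, 1e6), cm = c(0, 1))
  mks <- tibble::tibble(marker = c("a", "b"), chrom = "LG01",
                        pos = c(25e4, 75e4), freq = c(0.5, 0.5))
  fam <- simulate_families(cfg, markers = mks)
  d_cm <- 0.5
  r_true <- kosambi_inv(d_cm)  # ~ d/100 at this scale
  off <- fam$pedigree$id[!is.na(fam$pedigree$sire)]
  rec <- vapply(off, function(o) {
    co <- fam$truth$crossovers[[o]]$LG01
    pat <- sum(co$paternal > 25e4 & co$paternal <= 75e4) %% 2
    mat <- sum(co$maternal > 25e4 & co$maternal <= 75e4) %% 2
    c(pat, mat)
  }, numeric(2))
  r_hat <- mean(rec)
  se <- sqrt(r_true * (1 - r_true) / length(rec))
  expect_lt(abs(r_hat - r_true), 3 * se + 1e-9)
})

test_that("degenerate configurations raise config errors", {
  expect_error(sim_config(genome = genome_layout("LG01", 1e6),
                          sex_locus = list(chrom = "LG09", pos = 100)),
               class = "onilmap_config_error")
  expect_error(sim_config(genome = genome_layout("LG01", 1e6),
                          sex_locus = list(chrom = "LG01", pos = 2e6)),
               class = "onilmap_config_error")
  cfg <- tiny_config()
  cfg$site_density_bp <- 1e12   # no sites will be drawn
  expect_error(simulate_discovery_cohort(cfg), class = "onilmap_config_error")
})
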