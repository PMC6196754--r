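# The discovery filtering cascade and the exact Hardy-Weinberg test.

test_that("hwe_exact_test reproduces the enumerable small cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)            # monomorphic
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)         # het=0 least probable
  expect_equal(hwe_exact_test(0, 2, 0), 1)             # het=2 carries 2/3 + obs
})

test_that("hwe_exact_test matches full enumeration for counts up to 100 samples", {
  set.seed(42)
  for (rep in 1:400) {
    n <- sample(1:100, 1)
    n_ab <- sample(0:n, 1)
    rest <- n - n_ab
    n_aa <- if (rest > 0) sample(0:rest, 1) else 0
    n_bb <- rest - n_aa
    p_impl <- hwe_exact_test(n_aa, n_ab, n_bb)
    p_orc <- hwe_oracle(n_aa, n_ab, n_bb)
    expect_lt(abs(p_impl - p_orc), 1e-10)
  }
})

test_that("conditional heterozygote-count probabilities sum to one", {
  for (case in list(c(12, 30, 8), c(0, 1, 49), c(20, 0, 20))) {
    n <- sum(case)
    na <- 2 * min(case[1], case[3]) + case[2]
    ks <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    probs <- vapply(ks, function(k) {
      exp(k * log(2) + lgamma(n + 1) - lgamma((na - k) / 2 + 1) -
            lgamma(k + 1) - lgamma(n - (na + k) / 2 + 1) +
            lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1))
    }, numeric(1))
    expect_lt(abs(sum(probs) - 1), 1e-12)
  }
})

test_that("compute_maf follows the minor-allele convention", {
  expect_equal(compute_maf(c(0L, 0L, 1L)), 1 / 6)
  expect_equal(compute_maf(c(1L, 1L, 1L, 1L)), 0.5)
  expect_equal(compute_maf(c(2L, 2L, 2L)), 0)      # minor allele is ref
  expect_equal(compute_maf(c(0L, -1L, 1L)), 0.25)  # missing excluded
  expect_error(compute_maf(c(-1L, -1L)), class = "onilmap_undefined_maf")
})

# Build a hand-crafted variant table around a default-config edge case set.
filter_fixture <- function() {
  n <- 32
  het_row <- rep(1L, n)
  good_row <- rep(c(0L, 1L, 2L, 1L), n / 4)
  rare_row <- c(1L, rep(0L, n - 1))
  sites <- tibble::tibble(
    chrom = "LG01",
    pos = c(100, 206, 210, 400, 1000, 2000, 3000, 4000, 5000, 6000),
    id = paste0("v", 1:10),
    ref = c("A", "A", "AG", "C", "C", "A", "C", "A", "A", "A"),
    alt = c("G", "C", "A", "T", "G", "C,G", "T", "C", "C", "C"),
    qual = c(900, 900, 900, 900, 900, 900, 900, 20, 900, 900))
  gt <- rbind(good_row, good_row, good_row, good_row, good_row, good_row,
              het_row, good_row, rare_row, good_row)
  dp <- matrix(20, 10, n); dp[10, ] <- 22  # site 10: 704 summed reads
  gq <- matrix(60, 10, n); gq[5, 1:6] <- 25  # site 5: six genotypes masked
  rownames(gt) <- sites$id
  variant_table(sites, gt, dp, gq, samples = sprintf("s%02d", 1:n))
}

test_that("each cascade rule fires on its published boundary", {
  vt <- filter_fixture()
  res <- filter_discovery_variants(vt)
  reasons <- setNames(res$removed$reasons, res$removed$marker)
  expect_false("v1" %in% res$removed$marker)            # clean SNP kept
  expect_match(reasons[["v2"]], "NEAR_INDEL")           # 4 bp from the indel span
  expect_match(reasons[["v3"]], "NON_SNP")              # the indel itself
  expect_false("v4" %in% res$removed$marker)            # 185 bp away: kept
  expect_match(reasons[["v5"]], "LOW_CALLED")           # 26 called after GQ masking
  expect_match(reasons[["v6"]], "MULTIALLELIC")
  expect_match(reasons[["v7"]], "ALL_HET")
  expect_match(reasons[["v8"]], "QUAL")                 # QUAL <= 20 removed
  expect_match(reasons[["v9"]], "MAF")                  # 1/64 < 0.05
  expect_match(reasons[["v10"]], "DEPTH")               # 704 > 700 summed
})

test_that("indel proximity uses the padded reference span with the 5 bp rule", {
  mk_vt <- function(snp_pos) {
    sites <- tibble::tibble(chrom = "LG01", pos = c(snp_pos, 200),
                            id = c("snp", "indel"),
                            ref = c("A", "CT"), alt = c("G", "C"),
                            qual = c(900, 900))
    gt <- rbind(rep(c(0L, 1L), 16), rep(c(0L, 1L), 16))
    rownames(gt) <- sites$id
    variant_table(sites, gt, samples = sprintf("s%02d", 1:32))
  }
  # indel span 200-201; pad 5 bp: [195, 206]
  expect_true("snp" %in% filter_discovery_variants(mk_vt(196))$removed$marker)
  expect_true("snp" %in% filter_discovery_variants(mk_vt(206))$removed$marker)
  expect_false("snp" %in% filter_discovery_variants(mk_vt(207))$removed$marker)
  expect_false("snp" %in% filter_discovery_variants(mk_vt(194))$removed$marker)
})

test_that("depth boundary is exceeded-only and A/T-C/G pairs are removed", {
  sites <- tibble::tibble(chrom = "LG01", pos = c(100, 300), id = c("a", "b"),
                          ref = c("A", "C"), alt = c("G", "G"),
                          qual = c(900, 900))
  gt <- rbind(rep(c(0L, 1L), 16), rep(c(0L, 1L), 16))
  rownames(gt) <- sites$id
  dp <- rbind(rep(700 / 32, 32), rep(700 / 32, 32))
  vt <- variant_table(sites, gt, dp = dp, samples = sprintf("s%02d", 1:32))
  res <- filter_discovery_variants(vt)
  expect_false("a" %in% res$removed$marker)   # exactly 700 summed: kept
  expect_match(res$removed$reasons[res$removed$marker == "b"], "AT_CG")
})

test_that("removal reasons are recorded in cascade order", {
  sites <- tibble::tibble(chrom = "LG01", pos = 100, id = "x",
                          ref = "A", alt = "T", qual = 5)
  gt <- matrix(rep(1L, 32), 1, dimnames = list("x", NULL))
  vt <- variant_table(sites, gt, samples = sprintf("s%02d", 1:32))
  res <- filter_discovery_variants(vt)
  expect_match(res$removed$reasons, "^QUAL,AT_CG,ALL_HET")
})

test_that("filtering is idempotent on the kept set", {
  sim <- simulate_discovery_cohort(tiny_config(seed = 17))
  res <- filter_discovery_variants(sim$variants)
  res2 <- filter_discovery_variants(res$kept_table)
  expect_equal(sort(res2$kept), sort(res$kept))
  expect_equal(nrow(res2$removed), 0)
})

test_that("relaxing a site-level threshold never shrinks the kept set", {
  sim <- simulate_discovery_cohort(tiny_config(seed = 23))
  base <- filter_discovery_variants(sim$variants)
  relaxed <- list(
    filter_config(max_qual_removed = 10),
    filter_config(indel_window = 2),
    filter_config(max_depth = 1400),
    filter_config(min_called = 20),
    filter_config(min_maf = 0.01),
    filter_config(hwe_alpha = 0.005))
  for (cfg in relaxed) {
    kept <- filter_discovery_variants(sim$variants, cfg)$kept
    expect_true(all(base$kept %in% kept))
  }
})
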