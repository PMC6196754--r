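# Effect-prioritized selection and equidistant MAF-maximizing gap filling.

cand_tbl <- function(pos, maf, chrom = "LG01") {
  tibble::tibble(marker = paste0(chrom, "_", pos), chrom = chrom,
                 pos = pos, maf = maf)
}

test_that("effect picks respect the 10 kb spacing and the budget tie rule", {
  cand <- cand_tbl(c(0, 9999, 20000), c(0.1, 0.4, 0.2))
  ann <- tibble::tibble(marker = cand$marker, impact = "HIGH")
  picked <- select_effect_candidates(cand, ann)
  expect_equal(picked$pos, c(0, 20000))   # middle candidate within 10 kb

  cfg <- array_design_config(effect_budget = 1)
  cand2 <- cand_tbl(c(0, 50000), c(0.1, 0.3))
  ann2 <- tibble::tibble(marker = cand2$marker, impact = c("HIGH", "MODERATE"))
  expect_equal(select_effect_candidates(cand2, ann2, cfg)$pos, 50000)

  expect_equal(nrow(select_effect_candidates(
    cand, tibble::tibble(marker = character(), impact = character()))), 0)
  # LOW/MODIFIER annotations never qualify
  annlow <- tibble::tibble(marker = cand$marker, impact = "MODIFIER")
  expect_equal(nrow(select_effect_candidates(cand, annlow)), 0)
})

test_that("fill_gaps picks the window max-MAF candidate at each lattice target", {
  # 48 kb chromosome, candidates every 1 kb, MAF = pos / 1e5: the right edge
  # of each window maximizes MAF
  pos <- seq(1000, 48000, by = 1000)
  cand <- cand_tbl(pos, pos / 1e5)
  res <- fill_gaps(cand, cand[0, ], interval = 12000,
                   window_half_width = 6000, chrom_length = 48000)
  orc <- fill_gaps_oracle(cand, cand[0, ], 12000, 6000, 48000)
  expect_equal(res$added$marker, orc$added$marker)
  # right-edge picks; a pick sitting on a window edge covers the next target
  expect_equal(res$added$pos, c(18000, 42000))
  expect_length(res$unfilled, 0)
})

test_that("fill_gaps degenerate cases: exact-target singleton and idempotence", {
  lone <- cand_tbl(24000, 0.01)
  res <- fill_gaps(lone, lone[0, ], 12000, 6000, chrom_length = 30000)
  expect_equal(res$added$pos, 24000)          # alone in window: chosen anyway
  expect_equal(res$unfilled, c(12000))        # empty window reported

  # every target already satisfied: nothing added
  sel <- cand_tbl(c(12000, 24000), c(0.5, 0.5))
  res2 <- fill_gaps(cand_tbl(seq(1000, 24000, 1000), 0.2), sel, 12000, 6000,
                    chrom_length = 24000)
  expect_equal(nrow(res2$added), 0)
})

test_that("fill_gaps equals the per-target brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    len <- sample(5e4:3e5, 1)
    cand <- cand_tbl(sort(sample.int(len, n)), round(runif(n), 3))
    interval <- sample(c(8000, 12000, 33000), 1)
    whw <- interval / 2
    pre <- cand[sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.05, 0.95)), ]
    res <- fill_gaps(cand, pre, interval, whw, chrom_length = len)
    orc <- fill_gaps_oracle(cand, pre, interval, whw, len)
    expect_equal(res$added$marker, orc$added$marker)
    expect_equal(res$unfilled, orc$unfilled)
  }
})

test_that("select_array skips short scaffolds and fills long ones at 33 kb", {
  layout <- genome_layout(c("LG01", "scaf_long", "scaf_short"),
                          c(120000, 99000, 40000),
                          c(TRUE, FALSE, FALSE))
  cand <- dplyr::bind_rows(
    cand_tbl(seq(2000, 118000, 2000), 0.3),
    cand_tbl(seq(3000, 96000, 3000), 0.3, chrom = "scaf_long"),
    cand_tbl(seq(4000, 36000, 4000), 0.3, chrom = "scaf_short"))
  sel <- select_array(cand, layout = layout)
  chosen <- sel$chosen
  expect_equal(sum(chosen$chrom == "scaf_short"), 0)   # < 50 kb: nothing
  expect_equal(sum(chosen$chrom == "scaf_long"), floor(99000 / 33000))
  expect_equal(sum(chosen$chrom == "LG01"), floor(120000 / 12000))
  expect_true(all(chosen$provenance == "GAPFILL"))
})

test_that("selection is deterministic and respects the max-gap invariant", {
  set.seed(5)
  pos <- sort(sample.int(1.2e6, 900))
  cand <- cand_tbl(pos, round(runif(900), 3))
  layout <- genome_layout("LG01", 1.2e6)
  s1 <- select_array(cand, layout = layout)
  s2 <- select_array(cand, layout = layout)
  expect_identical(s1$chosen, s2$chosen)
  # dense candidates -> roughly one pick per 12 kb and bounded gaps
  expect_gt(nrow(s1$chosen), 0.8 * 100)
  gaps <- diff(s1$chosen$pos)
  expect_true(all(gaps <= 12000 + 2 * 6000 + 1))
})

test_that("include and reject lists behave as manual picks and rescue passes", {
  cand <- cand_tbl(seq(1000, 60000, 1000), seq(0.01, 0.6, by = 0.01)[1:60])
  layout <- genome_layout("LG01", 60000)
  base <- select_array(cand, layout = layout)
  top <- base$chosen$marker[1]
  resel <- select_array(cand, layout = layout, reject = top)
  expect_false(top %in% resel$chosen$marker)
  expect_gt(nrow(resel$chosen), 0)   # window refilled with the runner-up

  inc <- cand$marker[1]
  withinc <- select_array(cand, layout = layout, include = inc)
  expect_true(inc %in% withinc$chosen$marker)
  expect_equal(
    withinc$chosen$provenance[withinc$chosen$marker == inc][1],
    ifelse(inc %in% base$chosen$marker, "GAPFILL", "MITO_MANUAL"))
})

test_that("a variant chromosome missing from the layout is a consistency error", {
  cand <- cand_tbl(c(1000, 2000), c(0.1, 0.2), chrom = "LG99")
  expect_error(select_array(cand, layout = genome_layout("LG01", 1e5)),
               class = "onilmap_consistency_error")
})
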