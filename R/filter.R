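# Discovery-SNP filtering cascade: site quality, proximity to indels,
# multi-allelism, depth, A/T-C/G alleles, genotype-quality masking, call
# completeness, minor allele frequency, all-heterozygous sites, and an exact
# Hardy-Weinberg test.

#' Filter configuration
#'
#' Thresholds of the discovery-variant filtering cascade. Defaults follow
#' the published pipeline: remove sites with phred QUAL <= 20, within 5 bp of
#' an indel, with more than one alternate allele, with summed depth over 700
#' reads, with A/T or C/G alleles (these need twice the probes on the array),
#' mask individual genotypes with GQ < 30, then require >= 28 called samples,
#' MAF >= 0.05, not all-heterozygous, and an exact Hardy-Weinberg p >= 0.05.
#'
#' @param max_qual_removed Remove when site QUAL <= this (default 20).
#' @param indel_window Exclusion pad around each indel's reference span, bp
#'   (default 5).
#' @param max_depth Maximum summed sample depth (default 700).
#' @param disallowed_pairs Character vector of unordered allele pairs removed
#'   outright (default `c("A/T", "C/G")`).
#' @param min_gq Per-genotype phred quality below which the call is masked
#'   (default 30).
#' @param min_called Minimum non-missing samples after GQ masking
#'   (default 28).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param hwe_alpha Remove when the exact Hardy-Weinberg p-value is below
#'   this (default 0.05).
#' @param depth_scope `"site"` (default) compares `max_depth` against depth
#'   summed over samples; `"sample"` against each sample's depth.
#' @param indel_anchor_only When `TRUE`, measure indel proximity to the
#'   indel's anchor base instead of its full reference span (default FALSE).
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(max_qual_removed = 20, indel_window = 5,
                          max_depth = 700, disallowed_pairs = c("A/T", "C/G"),
                          min_gq = 30, min_called = 28, min_maf = 0.05,
                          hwe_alpha = 0.05, depth_scope = c("site", "sample"),
                          indel_anchor_only = FALSE) {
  depth_scope <- match.arg(depth_scope)
  assert_that(min_maf >= 0 && min_maf <= 0.5, "min_maf must be in [0, 0.5]")
  assert_that(all(c(max_qual_removed, indel_window, max_depth, min_gq,
                    min_called, hwe_alpha) >= 0), "thresholds must be >= 0")
  structure(list(max_qual_removed = max_qual_removed,
                 indel_window = indel_window, max_depth = max_depth,
                 disallowed_pairs = toupper(disallowed_pairs), min_gq = min_gq,
                 min_called = min_called, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, depth_scope = depth_scope,
                 indel_anchor_only = indel_anchor_only),
            class = "filter_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the probability of observing `k` heterozygotes among `N` diploid samples
#' carrying `nA` copies of one allele is
#' `N! / (n_AA! k! n_BB!) * 2^k * nA! nB! / (2N)!`, and the p-value sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one (two-sided probability-mass ordering, no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (each a vector; recycled together).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)   # 1/3
#' hwe_exact_test(10, 0, 0)  # monomorphic: 1
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  ln <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, ln); n_ab <- rep_len(n_ab, ln); n_bb <- rep_len(n_bb, ln)
  assert_that(all(n_aa >= 0 & n_ab >= 0 & n_bb >= 0), "counts must be >= 0")
  assert_that(all(n_aa + n_ab + n_bb >= 1), "at least one genotype required")
  vapply(seq_len(ln), function(i) {
    hwe_exact_one(n_aa[i], n_ab[i], n_bb[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * min(n_aa, n_bb) + n_ab        # minor allele count
  if (na == 0) return(1)
  ks <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- ks * log(2) + lgamma(n + 1) -
    lgamma((na - ks) / 2 + 1) - lgamma(ks + 1) - lgamma(n - (na + ks) / 2 + 1) +
    lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p <- exp(lp)
  p_obs <- p[ks == n_ab]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Minor allele frequency of a coded genotype vector
#'
#' @param genotypes Integer vector with codes in \{0, 1, 2, -1\}.
#' @return Minor-allele count / (2 x called samples), in \[0, 0.5\].
#' @examples
#' compute_maf(c(0, 0, 1))  # 1/6
#' @export
compute_maf <- function(genotypes) {
  assert_that(is_gt_code(genotypes), "genotype codes must be in {0, 1, 2, -1}")
  called <- genotypes >= 0
  assert_that(any(called), "MAF undefined: all genotypes missing",
              "onilmap_undefined_maf")
  alt <- sum(genotypes[called])
  tot <- 2 * sum(called)
  min(alt, tot - alt) / tot
}

#' Apply the discovery filtering cascade to a variant table
#'
#' Rules are applied in the published order and all violated rules are
#' recorded per marker: `QUAL` (site quality <= threshold), `NON_SNP`
#' (INDEL/MNP/other records leave the candidate set; indels additionally act
#' as proximity anchors), `NEAR_INDEL` (SNP position overlaps an indel's
#' reference span padded by `indel_window` bp), `MULTIALLELIC`, `DEPTH`,
#' `AT_CG`, then -- after masking individual genotypes with GQ below
#' `min_gq` -- `LOW_CALLED`, `MAF`, `ALL_HET`, and `HWE`.
#'
#' @param vt A [variant_table()] sorted by (chrom, pos).
#' @param config A [filter_config()].
#' @return An object of class `filter_result`: list with `kept` (marker
#'   ids), `removed` (tibble `marker`, `chrom`, `pos`, `reasons`
#'   comma-joined), `stats` (per-marker tibble with post-masking `n_called`,
#'   `maf`, `hwe_p`), and `kept_table` (the filtered [variant_table()] with
#'   GQ-masked genotypes).
#' @export
filter_discovery_variants <- function(vt, config = filter_config()) {
  stopifnot(inherits(vt, "variant_table"), inherits(config, "filter_config"))
  s <- vt$sites
  m <- nrow(s)
  reasons <- vector("list", m)
  add <- function(which, code) {
    for (i in which(which)) reasons[[i]] <<- c(reasons[[i]], code)
    invisible(NULL)
  }

  add(!is.na(s$qual) & s$qual <= config$max_qual_removed, "QUAL")
  is_snp <- s$variant_class == "SNP"
  add(!is_snp, "NON_SNP")

  # Indel proximity: pad each indel's reference span (or anchor base).
  ind <- which(s$variant_class == "INDEL")
  if (length(ind)) {
    span_end <- if (config$indel_anchor_only) s$pos[ind] else
      s$pos[ind] + nchar(s$ref[ind]) - 1
    zones <- tibble(chrom = s$chrom[ind],
                    lo = s$pos[ind] - config$indel_window,
                    hi = span_end + config$indel_window)
    near <- rep(FALSE, m)
    for (ch in unique(zones$chrom)) {
      z <- zones[zones$chrom == ch, , drop = FALSE]
      z <- z[order(z$lo), , drop = FALSE]
      # merge overlapping zones so findInterval() gives a single containment test
      hi_run <- cummax(z$hi)
      new_block <- c(TRUE, z$lo[-1] > hi_run[-nrow(z)])
      blk <- factor(cumsum(new_block), levels = unique(cumsum(new_block)))
      lo <- as.numeric(tapply(z$lo, blk, min))
      hi <- as.numeric(tapply(z$hi, blk, max))
      on_ch <- which(s$chrom == ch)
      j <- findInterval(s$pos[on_ch], lo)
      near[on_ch] <- j >= 1 & s$pos[on_ch] <= hi[pmax(j, 1)]
    }
    add(near & is_snp, "NEAR_INDEL")
  }

  n_alt <- lengths(strsplit(s$alt, ",", fixed = TRUE))
  add(n_alt > 1, "MULTIALLELIC")

  if (!is.null(vt$dp)) {
    if (config$depth_scope == "site") {
      add(rowSums(vt$dp, na.rm = TRUE) > config$max_depth, "DEPTH")
    } else {
      add(apply(vt$dp, 1, function(d) any(d > config$max_depth, na.rm = TRUE)),
          "DEPTH")
    }
  }

  pair <- paste(pmin(s$ref, s$alt), pmax(s$ref, s$alt), sep = "/")
  add(is_snp & n_alt == 1 & toupper(pair) %in% config$disallowed_pairs, "AT_CG")

  # GQ < min_gq masks the individual genotype (absent GQ is left alone).
  gt <- vt$gt
  if (!is.null(vt$gq)) gt[!is.na(vt$gq) & vt$gq < config$min_gq] <- -1L

  called <- gt >= 0L
  n_called <- rowSums(called)
  add(n_called < config$min_called, "LOW_CALLED")

  alt_count <- rowSums(gt * (gt > 0L))
  maf <- ifelse(n_called > 0,
                pmin(alt_count, 2 * n_called - alt_count) / (2 * n_called), NA_real_)
  add(!is.na(maf) & maf < config$min_maf, "MAF")
  add(n_called > 0 & rowSums(gt == 1L) == n_called, "ALL_HET")

  n0 <- rowSums(gt == 0L); n1 <- rowSums(gt == 1L); n2 <- rowSums(gt == 2L)
  hwe_p <- rep(NA_real_, m)
  ok <- n_called > 0
  hwe_p[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
  add(!is.na(hwe_p) & hwe_p < config$hwe_alpha, "HWE")

  keep <- lengths(reasons) == 0
  kept_vt <- variant_table(s[keep, , drop = FALSE],
                           gt = gt[keep, , drop = FALSE],
                           dp = if (!is.null(vt$dp)) vt$dp[keep, , drop = FALSE],
                           gq = if (!is.null(vt$gq)) vt$gq[keep, , drop = FALSE],
                           samples = vt$samples)
  structure(list(
    kept = s$id[keep],
    removed = tibble(marker = s$id[!keep], chrom = s$chrom[!keep],
                     pos = s$pos[!keep],
                     reasons = vapply(reasons[!keep], paste, character(1),
                                      collapse = ",")),
    stats = tibble(marker = s$id, chrom = s$chrom, pos = s$pos,
                   variant_class = s$variant_class, n_called = n_called,
                   maf = maf, hwe_p = hwe_p, kept = keep),
    kept_table = kept_vt,
    config = config
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> kept ", length(x$kept), " of ",
      nrow(x$stats), " records\n", sep = "")
  if (nrow(x$removed)) {
    tab <- sort(table(unlist(strsplit(x$removed$reasons, ","))), decreasing = TRUE)
    cat("  removal reasons:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a filter result
#'
#' @param x A `filter_result`.
#' @param ... Unused.
#' @return Per-marker tibble with call statistics and a `kept` flag.
#' @method tidy filter_result
#' @export
tidy.filter_result <- function(x, ...) x$stats

#' One-line summary of a filter result
#'
#' @param x A `filter_result`.
#' @param ... Unused.
#' @return One-row tibble: input records, kept, removed.
#' @method glance filter_result
#' @export
glance.filter_result <- function(x, ...) {
  tibble(n_input = nrow(x$stats), n_kept = length(x$kept),
         n_removed = nrow(x$removed))
}
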