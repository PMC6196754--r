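# Independent oracles, deliberately written as brute-force enumerations so
# they share no code with the implementation they check.

# Exact Hardy-Weinberg test by full enumeration over heterozygote counts,
# computing each outcome probability with exact rational-ish arithmetic in
# log space via factorials only.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  ks <- seq(0, n)
  probs <- vapply(ks, function(k) {
    aa <- (n_a - k) / 2
    bb <- (n_b - k) / 2
    if (aa < 0 || bb < 0 || aa %% 1 != 0 || bb %% 1 != 0) return(0)
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(k) - lfactorial(bb) +
          k * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n))
  }, numeric(1))
  p_obs <- probs[ks == n_ab]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Per-target argmax gap-filling oracle: literal restatement of the window
# rule, evaluated independently per target with a plain loop.
fill_gaps_oracle <- function(candidates, already_selected, interval, whw,
                             chrom_length) {
  targets <- seq(interval, chrom_length, by = interval)
  sel_pos <- already_selected$pos
  added <- candidates[0, ]
  unfilled <- numeric(0)
  for (t in targets) {
    covered <- FALSE
    for (p in c(sel_pos, added$pos)) {
      if (abs(p - t) <= whw) covered <- TRUE
    }
    if (covered) next
    best <- NULL
    for (i in seq_len(nrow(candidates))) {
      row <- candidates[i, ]
      if (row$pos < t - whw || row$pos > t + whw) next
      if (row$pos %in% c(sel_pos, added$pos)) next
      if (is.null(best)) { best <- row; next }
      better <- row$maf > best$maf ||
        (row$maf == best$maf && abs(row$pos - t) < abs(best$pos - t)) ||
        (row$maf == best$maf && abs(row$pos - t) == abs(best$pos - t) &&
           row$pos < best$pos)
      if (better) best <- row
    }
    if (is.null(best)) unfilled <- c(unfilled, t) else added <- rbind(added, best)
  }
  list(added = added, unfilled = unfilled)
}

# Exhaustive minimum-crossover phasing over all 2^M phase vectors. The cost
# of a phase vector counts, between each pair of adjacent informative
# markers, the offspring resolved at both whose haplotype-of-origin flips.
phase_oracle <- function(A) {
  m <- ncol(A)
  best <- Inf
  for (code in 0:(2^m - 1)) {
    phase <- as.integer(intToBits(code))[seq_len(m)]
    H <- abs(sweep(A, 2, phase))
    total <- 0
    for (j in seq_len(m - 1)) {
      both <- !is.na(H[, j]) & !is.na(H[, j + 1])
      total <- total + sum(H[both, j] != H[both, j + 1])
    }
    if (total < best) best <- total
  }
  best
}

# Simple pairwise crossover-count check helper: count flips per offspring
# between consecutive adjacent informative markers (resolved pairs only).
pairwise_flips <- function(A) {
  m <- ncol(A)
  total <- 0
  for (j in seq_len(m - 1)) {
    both <- !is.na(A[, j]) & !is.na(A[, j + 1])
    d <- sum(A[both, j] != A[both, j + 1])
    total <- total + min(d, sum(both) - d)
  }
  total
}
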