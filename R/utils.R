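# Internal helpers shared across modules.

# Round half away from zero, the convention used by the printed summary tables
# (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_onilmap <- function(msg, class) {
  rlang::abort(msg, class = c(class, "onilmap_error"))
}

assert_that <- function(ok, msg, class = "onilmap_domain_error") {
  if (!isTRUE(ok)) abort_onilmap(msg, class)
  invisible(TRUE)
}

# Genotype codes: 0 hom-ref, 1 het, 2 hom-alt, -1 missing.
GT_CODES <- c(-1L, 0L, 1L, 2L)

is_gt_code <- function(x) {
  all(x %in% GT_CODES)
}

# Normalise a sex encoding to "M"/"F"/NA. Accepts the pedigree-file convention
# (12 = male, 11 = female) as well as M/F and male/female strings.
normalize_sex <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("12", "M", "m", "male", "Male", "1")] <- "M"
  out[x %in% c("11", "F", "f", "female", "Female", "2")] <- "F"
  out
}
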