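# Readers/writers for the standard formats the pipeline touches, plus the two
# compact in-memory containers (variant_table, genotype_matrix).

#' Variant table container
#'
#' Holds discovery-sequencing variants: one row of site metadata per record
#' plus marker x sample matrices of genotype codes, read depths and genotype
#' qualities. Genotypes are coded 0 (hom-ref), 1 (het), 2 (hom-alt),
#' -1 (missing); depth/GQ use `NA` for "absent" so that threshold rules can
#' distinguish absent from zero.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (comma-separated for multi-allelic records) and `qual`.
#' @param gt Integer matrix (markers x samples) of genotype codes.
#' @param dp,gq Optional numeric matrices (markers x samples) of per-sample
#'   depth and genotype quality; `NULL` when the channel is absent.
#' @param samples Character vector of sample ids (columns of the matrices).
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp = NULL, gq = NULL, samples = colnames(gt)) {
  sites <- as_tibble(sites)
  assert_that(all(c("chrom", "pos", "id", "ref", "alt", "qual") %in% names(sites)),
              "sites must have chrom, pos, id, ref, alt, qual")
  assert_that(all(sites$pos >= 1), "pos must be >= 1")
  assert_that(all(nchar(sites$ref) > 0) && all(nchar(sites$alt) > 0),
              "ref and alt must be non-empty")
  gt <- as.matrix(gt); storage.mode(gt) <- "integer"
  assert_that(nrow(gt) == nrow(sites), "gt rows must match sites")
  assert_that(is_gt_code(gt), "genotype codes must be in {0, 1, 2, -1}")
  if (!is.null(dp)) assert_that(all(dim(dp) == dim(gt)), "dp dimensions must match gt")
  if (!is.null(gq)) assert_that(all(dim(gq) == dim(gt)), "gq dimensions must match gt")
  sites$variant_class <- classify_variant(sites$ref, sites$alt)
  rownames(gt) <- sites$id
  colnames(gt) <- samples
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = as.character(samples)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$sites), " records x ", length(x$samples),
      " samples\n", sep = "")
  print(utils::head(x$sites, 5))
  invisible(x)
}

# SNP iff ref and every alt have length 1; unequal lengths -> INDEL;
# equal lengths > 1 -> MNP.
classify_variant <- function(ref, alt) {
  vapply(seq_along(ref), function(i) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    if (nchar(ref[i]) == 1 && all(nchar(alts) == 1)) return("SNP")
    if (any(nchar(alts) != nchar(ref[i]))) return("INDEL")
    if (nchar(ref[i]) > 1) return("MNP")
    "OTHER"
  }, character(1))
}

#' Genotype matrix container
#'
#' Coded array genotypes for samples x markers, with marker physical
#' coordinates. Markers are kept sorted by (chrom, pos) with strictly
#' increasing positions within a chromosome.
#'
#' @param codes Integer matrix samples x markers with values in
#'   \{0, 1, 2, -1\}.
#' @param markers Tibble with columns `marker`, `chrom`, `pos`.
#' @param samples Character vector of sample ids (rows).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, markers, samples = rownames(codes)) {
  markers <- as_tibble(markers)
  assert_that(all(c("marker", "chrom", "pos") %in% names(markers)),
              "markers must have marker, chrom, pos")
  codes <- as.matrix(codes); storage.mode(codes) <- "integer"
  assert_that(ncol(codes) == nrow(markers), "codes columns must match markers")
  assert_that(nrow(codes) == length(samples), "codes rows must match samples")
  assert_that(is_gt_code(codes), "genotype codes must be in {0, 1, 2, -1}")
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  dup <- stats::ave(markers$pos, markers$chrom,
                    FUN = function(p) c(FALSE, diff(p) <= 0))
  assert_that(!any(dup == 1), "marker positions must be strictly increasing within chrom")
  rownames(codes) <- samples
  colnames(codes) <- markers$marker
  structure(list(codes = codes, markers = markers, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      nrow(x$markers), " markers (",
      length(unique(x$markers$chrom)), " chromosomes)\n", sep = "")
  invisible(x)
}

#' Convert a variant table to a genotype matrix
#'
#' @param vt A [variant_table()].
#' @return A [genotype_matrix()] (samples x markers, markers sorted by
#'   chrom/pos).
#' @export
as_genotype_matrix <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  genotype_matrix(t(vt$gt),
                  markers = tibble(marker = vt$sites$id,
                                   chrom = vt$sites$chrom,
                                   pos = vt$sites$pos),
                  samples = vt$samples)
}

#' Read a VCF file into a variant table
#'
#' Parses a VCF v4.x file (GT required; DP and GQ used when present in
#' FORMAT). Multi-allelic records are preserved as single records; any
#' genotype carrying an alternate allele index > 0 counts that allele as
#' "alt" for the 0/1/2 coding. Phased separators (`|`) are accepted and
#' treated as unphased.
#'
#' @param path Path to a VCF file (plain or bgzip; anything vcfR reads).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path), "onilmap_format_error")
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort_onilmap(
      paste0("malformed VCF '", path, "': ", conditionMessage(e)),
      "onilmap_format_error")
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1] %||% character(0)
  if (n == 0) {
    return(variant_table(
      tibble(chrom = character(), pos = numeric(), id = character(),
             ref = character(), alt = character(), qual = numeric()),
      gt = matrix(integer(), 0, length(samples), dimnames = list(NULL, samples)),
      samples = samples))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  bad <- !is.na(gt_raw) & !grepl("^\\.?[0-9.]*[/|]\\.?[0-9.]*$", gt_raw) &
    !grepl("^[0-9.]+$", gt_raw)
  # ploidy check: require exactly one separator (diploid) or fully missing
  ploidy_bad <- !is.na(gt_raw) &
    (nchar(gsub("[^/|]", "", gt_raw)) != 1L) & gt_raw != "."
  if (any(ploidy_bad)) {
    line <- which(rowSums(ploidy_bad) > 0)[1]
    abort_onilmap(paste0("non-diploid genotype at record ", line),
                  "onilmap_format_error")
  }
  codes <- gt_to_code(gt_raw)
  has <- function(el) any(grepl(el, v@gt[, "FORMAT"], fixed = TRUE))
  dp <- if (has("DP")) suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE)) else NULL
  gq <- if (has("GQ")) suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE)) else NULL
  id <- fix$ID
  miss_id <- is.na(id) | id == "."
  id[miss_id] <- paste0(fix$CHROM[miss_id], "_", fix$POS[miss_id])
  variant_table(
    tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS), id = id,
           ref = fix$REF, alt = fix$ALT,
           qual = suppressWarnings(as.numeric(fix$QUAL))),
    gt = codes, dp = dp, gq = gq, samples = samples)
}

# "0/1"-style strings -> 0/1/2/-1 codes; any allele index > 0 counts as alt.
gt_to_code <- function(gt_raw) {
  n <- nrow(gt_raw); m <- ncol(gt_raw)
  a <- sub("[/|].*$", "", gt_raw)
  b <- sub("^.*[/|]", "", gt_raw)
  code <- function(x) ifelse(x %in% c(".", "", NA), NA_integer_,
                             as.integer(as.integer(x) > 0))
  ca <- suppressWarnings(code(a)); cb <- suppressWarnings(code(b))
  out <- ca + cb
  out[is.na(out)] <- -1L
  matrix(as.integer(out), n, m, dimnames = dimnames(gt_raw))
}

#' Write a variant table to a plain-text VCF file
#'
#' Emits VCF v4.2 with FORMAT GT:DP:GQ (DP/GQ omitted when absent from the
#' table). Round-tripping through [read_vcf()] reproduces genotype codes,
#' positions and alleles exactly. Het genotypes are written as `0/1`,
#' hom-alt as `1/1` (allele indices above 1 are only meaningful on input).
#'
#' @param vt A [variant_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort_onilmap(
                    paste0("cannot write '", path, "'"), "onilmap_io_error"))
  on.exit(close(con))
  fmt <- c("GT",
           if (!is.null(vt$dp)) "DP",
           if (!is.null(vt$gq)) "GQ")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=onilmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(vt$dp)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    if (!is.null(vt$gq)) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(vt$samples)) c("FORMAT", vt$samples)), collapse = "\t"))
  writeLines(header, con)
  n <- nrow(vt$sites)
  if (n > 0) {
    idx <- ifelse(vt$gt < 0L, NA_integer_, vt$gt + 1L)
    gt_str <- matrix(c("0/0", "0/1", "1/1")[idx], nrow(vt$gt), ncol(vt$gt))
    gt_str[is.na(gt_str)] <- "./."
    cell <- gt_str
    if (!is.null(vt$dp)) {
      d <- ifelse(is.na(vt$dp), ".", format(vt$dp, trim = TRUE, scientific = FALSE))
      cell <- matrix(paste(cell, d, sep = ":"), n)
    }
    if (!is.null(vt$gq)) {
      g <- ifelse(is.na(vt$gq), ".", format(vt$gq, trim = TRUE, scientific = FALSE))
      cell <- matrix(paste(cell, g, sep = ":"), n)
    }
    qual <- ifelse(is.na(vt$sites$qual), ".",
                   format(vt$sites$qual, trim = TRUE, scientific = FALSE))
    left <- paste(vt$sites$chrom, format(vt$sites$pos, trim = TRUE, scientific = FALSE),
                  vt$sites$id, vt$sites$ref, vt$sites$alt, qual, "PASS", ".",
                  sep = "\t")
    if (length(vt$samples)) {
      left <- paste(left, paste(fmt, collapse = ":"),
                    apply(cell, 1, paste, collapse = "\t"), sep = "\t")
    }
    writeLines(left, con)
  }
  invisible(path)
}

# Named schemas for the tab-separated tables the pipeline exchanges.
table_schemas <- list(
  map = c("lg", "marker", "bp", "cm_female", "cm_male", "cm_sexavg"),
  pedigree = c("id", "sire", "dam", "sex"),
  sex = c("id", "sex"),
  annotation = c("marker", "impact"),
  layout = c("name", "length_bp", "assigned")
)

#' Read a typed tab-separated table
#'
#' Reads one of the pipeline's TSV exchange formats and checks its mandatory
#' columns. Unknown columns are preserved untouched. Schemas:
#' \describe{
#'   \item{map}{`lg, marker, bp, cm_female, cm_male, cm_sexavg`}
#'   \item{pedigree}{`id, sire, dam, sex` (sire/dam `"0"` = founder,
#'     recoded to `NA`)}
#'   \item{sex}{`id, sex` (12 = male, 11 = female; also accepts M/F)}
#'   \item{annotation}{`marker, impact` (HIGH/MODERATE/LOW/MODIFIER)}
#'   \item{layout}{`name, length_bp, assigned`}
#' }
#'
#' @param path Path to a tab-separated file with a header line.
#' @param schema One of `"map"`, `"pedigree"`, `"sex"`, `"annotation"`,
#'   `"layout"`.
#' @return A tibble with typed mandatory columns.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  cols <- table_schemas[[schema]]
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort_onilmap(paste0("schema '", schema, "': missing mandatory column(s) ",
                         paste(missing_cols, collapse = ", ")),
                  "onilmap_schema_error")
  }
  num <- intersect(names(x), c("bp", "pos", "cm_female", "cm_male", "cm_sexavg",
                               "length_bp", "maf"))
  for (cc in num) x[[cc]] <- as.numeric(x[[cc]])
  if (schema == "pedigree") {
    x$sire[x$sire %in% "0"] <- NA_character_
    x$dam[x$dam %in% "0"] <- NA_character_
    x$sex <- normalize_sex(x$sex)
  }
  if (schema == "sex") x$sex <- normalize_sex(x$sex)
  if (schema == "layout") x$assigned <- as.logical(as.numeric(x$assigned) |
                                                     x$assigned %in% c("TRUE", "true"))
  if (schema == "annotation") x$impact <- toupper(x$impact)
  x
}

#' Write a tibble as a tab-separated table
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write the genotype-matrix TSV exchange format
#'
#' One row per sample; the first column (`sample`) holds sample ids and the
#' remaining columns, named `chrom:pos:marker`, hold genotype codes
#' 0/1/2/-1.
#'
#' @param path Path to a tab-separated file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- x[[1]]
  codes <- as.matrix(x[, -1])
  parts <- strsplit(colnames(codes), ":", fixed = TRUE)
  genotype_matrix(codes,
                  tibble(marker = vapply(parts, `[`, "", 3),
                         chrom = vapply(parts, `[`, "", 1),
                         pos = as.numeric(vapply(parts, `[`, "", 2))),
                  samples = ids)
}

#' @rdname read_genotypes_tsv
#' @param gm A [genotype_matrix()].
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- as.data.frame(gm$codes)
  colnames(out) <- paste(gm$markers$chrom, gm$markers$pos, gm$markers$marker,
                         sep = ":")
  out <- cbind(sample = gm$samples, out)
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Tidy a variant table into one row per record
#'
#' @param x A [variant_table()].
#' @param ... Unused.
#' @return The site tibble with per-marker call statistics appended
#'   (`n_called`, `maf`).
#' @method tidy variant_table
#' @export
tidy.variant_table <- function(x, ...) {
  called <- x$gt >= 0L
  n_called <- rowSums(called)
  alt <- rowSums(x$gt * (x$gt > 0L))
  maf <- ifelse(n_called > 0, pmin(alt, 2 * n_called - alt) / (2 * n_called), NA_real_)
  dplyr::mutate(x$sites, n_called = n_called, maf = maf)
}

#' Tidy a genotype matrix into its marker map
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Marker tibble with per-marker genotype counts.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  g <- x$codes
  dplyr::mutate(x$markers,
                n0 = colSums(g == 0L), n1 = colSums(g == 1L),
                n2 = colSums(g == 2L), n_missing = colSums(g == -1L))
}
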