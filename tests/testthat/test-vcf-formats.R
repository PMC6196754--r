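# Readers/writers and the coded containers.

test_that("read_vcf maps GT/DP/GQ fields, missing codes and variant classes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(path)
  vt <- read_vcf(path)
  expect_s3_class(vt, "variant_table")
  expect_equal(vt$samples, c("s1", "s2"))
  # direct field mapping
  expect_equal(unname(vt$gt["m1", ]), c(1L, 2L))
  expect_equal(unname(vt$dp["m1", ]), c(30, 22))
  expect_equal(unname(vt$gq["m1", ]), c(45, 80))
  # ./. -> -1, absent DP/GQ -> NA
  expect_equal(unname(vt$gt["m2", "s2"]), -1L)
  expect_true(is.na(vt$dp["m2", "s2"]))
  # length rule: REF=AC ALT=A is an indel; multi-allelic kept as one record
  expect_equal(vt$sites$variant_class, c("SNP", "INDEL", "SNP"))
  expect_equal(vt$sites$alt[3], "G,T")
  # 0/2 counts the second alternate as alt dosage 1
  expect_equal(unname(vt$gt["m3", "s1"]), 1L)
})

test_that("VCF round-trip is lossless for genotypes, positions and alleles", {
  sim <- simulate_discovery_cohort(tiny_config(seed = 3))
  # inject missing genotypes: the writer must keep cell alignment intact
  set.seed(1)
  sim$variants$gt[sample(length(sim$variants$gt), 50)] <- -1L
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, path)
  back <- read_vcf(path)
  expect_equal(unname(back$gt), unname(sim$variants$gt))
  expect_equal(back$sites$pos, sim$variants$sites$pos)
  expect_equal(back$sites$ref, sim$variants$sites$ref)
  expect_equal(back$sites$alt, sim$variants$sites$alt)
  expect_equal(back$sites$variant_class, sim$variants$sites$variant_class)
  expect_equal(back$gq, sim$variants$gq, ignore_attr = TRUE)
})

test_that("an empty table writes a header-only VCF and a GQ-less table omits GQ", {
  empty <- variant_table(
    tibble::tibble(chrom = character(), pos = numeric(), id = character(),
                   ref = character(), alt = character(), qual = numeric()),
    gt = matrix(integer(), 0, 2, dimnames = list(NULL, c("a", "b"))))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  lines <- readLines(path)
  expect_true(all(grepl("^#", lines)))
  expect_equal(nrow(read_vcf(path)$sites), 0)

  no_gq <- variant_table(
    tibble::tibble(chrom = "LG01", pos = 5, id = "x", ref = "A", alt = "C",
                   qual = 10),
    gt = matrix(1L, 1, 1, dimnames = list(NULL, "s1")))
  write_vcf(no_gq, path)
  expect_false(any(grepl("GQ", readLines(path))))
})

test_that("non-diploid genotypes are a format error naming the record", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("LG01", "10", "m1", "A", "G", "50", "PASS", ".", "GT", "0/1/1",
          sep = "\t")), path)
  expect_error(read_vcf(path), class = "onilmap_format_error")
})

test_that("read_table enforces schemas and applies the field conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lg\tmarker\tbp\tcm_female\tcm_male\tcm_sexavg",
               "LG01\tm1\t12000\t0.0\t0.0\t0.0"), path)
  tbl <- read_table(path, "map")
  expect_equal(tbl$bp, 12000)

  writeLines(c("id\tsex", "s17\t12", "s18\t11"), path)
  sexes <- read_table(path, "sex")
  expect_equal(sexes$sex, c("M", "F"))   # 12 = male, 11 = female

  writeLines(c("id\tsire\tdam\tsex", "f1\t0\t0\t12", "o1\tf1\td1\t11"), path)
  ped <- read_table(path, "pedigree")
  expect_true(is.na(ped$sire[1]))        # "0" is the founder sentinel
  expect_equal(ped$sire[2], "f1")

  writeLines(c("lg\tmarker", "LG01\tm1"), path)
  expect_error(read_table(path, "map"), class = "onilmap_schema_error")
  expect_error(read_table(path, "map"), "bp")
})

test_that("the genotype-matrix TSV exchange format round-trips", {
  fx <- map_fixture(seed = 9, length_bp = 3e5, site_density_bp = 10000,
                    n_families = 2, offspring = 8L,
                    error_rate = 0.01, missing_rate = 0.02)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(fx$fam$genotypes, path)
  back <- read_genotypes_tsv(path)
  expect_identical(back$codes, fx$fam$genotypes$codes)
  expect_equal(back$markers, fx$fam$genotypes$markers)
})

test_that("genotype_matrix enforces sorted unique coordinates and code range", {
  mk <- tibble::tibble(marker = c("b", "a"), chrom = "LG01", pos = c(20, 10))
  gm <- genotype_matrix(matrix(c(0L, 1L), 1), mk, samples = "s1")
  expect_equal(gm$markers$marker, c("a", "b"))        # sorted by position
  expect_equal(unname(gm$codes[1, ]), c(1L, 0L))      # codes follow the sort
  expect_error(
    genotype_matrix(matrix(0L, 1, 2),
                    tibble::tibble(marker = c("a", "b"), chrom = "LG01",
                                   pos = c(5, 5)), "s1"),
    "strictly increasing")
  expect_error(
    genotype_matrix(matrix(3L, 1, 1),
                    tibble::tibble(marker = "a", chrom = "LG01", pos = 1), "s1"),
    "codes")
})
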