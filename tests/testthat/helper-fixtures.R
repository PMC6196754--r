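# Small in-code fixtures shared across test files.

tiny_genome <- function() {
  genome_layout(c("LG01", "scaf_big", "scaf_small"),
                c(6e5, 8e4, 3e4),
                c(TRUE, FALSE, FALSE))
}

tiny_config <- function(seed = 7, ...) {
  sim_config(genome = tiny_genome(), seed = seed,
             n_families = 4, offspring_per_family = 10L,
             n_sires = 3, n_dams = 3, ...)
}

# Hand-written VCF exercising GT/DP/GQ parsing, missing codes and classes.
write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("LG01", "101", "m1", "A", "G", "900", "PASS", ".",
          "GT:DP:GQ", "0/1:30:45", "1/1:22:80", sep = "\t"),
    paste("LG01", "205", "m2", "AC", "A", "50", "PASS", ".",
          "GT:DP:GQ", "0/0:18:60", "./.:.:.", sep = "\t"),
    paste("LG01", "390", "m3", "C", "G,T", "75", "PASS", ".",
          "GT:DP:GQ", "0/2:25:50", "0/0:31:70", sep = "\t"))
  writeLines(lines, path)
  path
}

# A deterministic family fixture for the mapping tests: one LG, moderate
# marker count, configurable noise.
map_fixture <- function(seed = 11, error_rate = 0, missing_rate = 0,
                        length_bp = 40e6, site_density_bp = 60000,
                        n_families = 12, offspring = 12L) {
  cfg <- sim_config(genome = genome_layout("LG01", length_bp),
                    seed = seed, n_families = n_families,
                    offspring_per_family = offspring,
                    n_sires = 4, n_dams = 4,
                    error_rate = error_rate, missing_rate = missing_rate,
                    site_density_bp = site_density_bp)
  fam <- simulate_families(cfg)
  list(cfg = cfg, fam = fam,
       ped = fam$pedigree[!is.na(fam$pedigree$sire), ])
}
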