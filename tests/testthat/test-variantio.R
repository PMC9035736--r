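write_mini_vcf <- function(records, samples = c("s1", "s2", "s3")) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

test_that("read_vcf maps GT strings to genotype codes", {
  info <- "DP=30;QD=10;FS=1;MQ=50;SOR=1"
  path <- write_mini_vcf(c(
    paste("chr1", 100, ".", "A", "G", "50", ".", info, "GT", "0/0", "0|1", "1/1", sep = "\t"),
    paste("chr1", 200, ".", "T", "C", "50", ".", info, "GT", ".|.", "1/0", "./1", sep = "\t"),
    paste("chr1", 300, ".", "G", "A,T", "50", ".", info, "GT", "1/2", "2/2", "0/0", sep = "\t")
  ))
  m <- read_vcf(path)
  expect_identical(m$gt[1, ], c(s1 = "HOM_REF", s2 = "HET", s3 = "HOM_ALT"))
  expect_identical(unname(m$gt[2, ]), c("MISSING", "HET", "MISSING"))
  # allele indices beyond 1 are uncallable under the biallelic encoding
  expect_identical(unname(m$gt[3, ]), c("MISSING", "MISSING", "HOM_REF"))
  expect_identical(m$variant_class, c("SNP", "SNP", "SNP"))
  expect_equal(m$mean_depth, rep(10, 3))
})

test_that("read_vcf refuses a VCF without GT", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t1\t.\tA\tG\t50\t.\t.\tAD\t3,4"
  ), path)
  expect_error(read_vcf(path), "GT")
})

test_that("simulator VCFs round-trip through read_vcf", {
  sim <- sim_fixture(sites_per_chromosome = 250, seed = 17)
  sites <- read_vcf(sim$ancestor_b_vcf)
  expect_equal(nrow(sites), 500)
  expect_identical(colnames(sites$gt), sprintf("B%02d", 1:18))
  # re-write what was read and read it again: an idempotent representation
  back <- crossorigin:::write_vcf_file(
    sites, sites$gt, withr::local_tempfile(fileext = ".vcf"),
    tibble::tibble(chrom = unique(sites$chrom), length = max(sites$pos))
  )
  sites2 <- read_vcf(back)
  expect_identical(sites2$gt, sites$gt)
  expect_equal(sites2[names(sites2) != "gt"], sites[names(sites) != "gt"])
})

test_that("hard filter applies each clause strictly as written", {
  base <- tibble::tibble(
    chrom = "chr1", pos = 1:4 * 10L, ref = c("A", "A", "A", "AT"),
    alt = c("G", "G", "G", "A"),
    variant_class = c("SNP", "SNP", "SNP", "DELETION"),
    qual = c(29.9, 30.0, 50, 50), qd = c(10, 10, 10, 10),
    fs = c(1, 1, 1, 150), mq = c(50, 50, 39.9, 50), sor = c(1, 1, 1, 9.9)
  )
  kept <- hard_filter_sites(base, filter_config())
  # QUAL 29.9 fails QUAL < 30; QUAL exactly 30 passes; MQ 39.9 fails;
  # the indel with FS 150 and SOR 9.9 passes the indel bounds (200 / 10)
  expect_identical(kept$pos, c(20L, 40L))
})

test_that("sites with missing annotations are removed with a warning", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "G",
    variant_class = "SNP", qual = c(50, 50), qd = c(NA, 10),
    fs = 1, mq = 50, sor = 1
  )
  expect_warning(kept <- hard_filter_sites(s), "missing filter annotations")
  expect_identical(kept$pos, 20L)
})

test_that("hard filter agrees with a site-by-site clause oracle", {
  sim <- sim_fixture(sites_per_chromosome = 500, seed = 19)
  sites <- read_vcf(sim$ancestor_a_vcf)
  cfg <- filter_config()
  expect_identical(hard_filter_sites(sites, cfg)$pos,
                   sites$pos[oracle_hard_filter_keep(sites, cfg)])
})

test_that("SNP cluster filter handles the textbook layouts", {
  mk <- function(pos, class = "SNP") {
    tibble::tibble(chrom = "chr1", pos = as.integer(pos), variant_class = class)
  }
  expect_identical(snp_cluster_filter(mk(c(100, 105, 109)))$pos, integer(0))
  expect_identical(snp_cluster_filter(mk(c(100, 120, 140)))$pos, c(100L, 120L, 140L))
  expect_identical(snp_cluster_filter(mk(c(100, 105, 109, 200)))$pos, 200L)
  # indels neither trigger nor suffer removal
  mixed <- mk(c(100, 104, 106, 109), class = c("SNP", "DELETION", "SNP", "SNP"))
  expect_identical(snp_cluster_filter(mixed)$pos, c(104L))
  no_trigger <- mk(c(100, 105, 109), class = c("SNP", "INSERTION", "SNP"))
  expect_identical(snp_cluster_filter(no_trigger)$pos, c(100L, 105L, 109L))
  expect_error(snp_cluster_filter(mk(c(109, 100, 105))), "sorted")
})

test_that("cluster filter agrees with a window-scan oracle on simulated sites", {
  sim <- simulate_dataset(sim_params(sites_per_chromosome = 600, n_chromosomes = 2,
                                     seed = 23))
  sites <- read_vcf(sim$ancestor_b_vcf)
  # densify positions so clusters actually occur
  sites$pos <- as.integer(ceiling(sites$pos / 12))
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
  got <- snp_cluster_filter(sites, 3, 10)
  expect_identical(got$pos, sites$pos[oracle_cluster_keep(sites, 3, 10)])
})

test_that("cohort filter keeps the inclusive MAF boundary and drops missing-heavy sites", {
  mk <- function(gt) {
    tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                   variant_class = "SNP", mean_depth = 10,
                   gt = matrix(gt, nrow = 1))
  }
  boundary <- mk(c(rep("HOM_REF", 19), "HOM_ALT"))   # MAF = 2/40 = 0.05
  expect_equal(nrow(cohort_filter(boundary)), 1)
  missing11 <- mk(c(rep("MISSING", 11), rep("HET", 9)))  # called 9/20 < 0.5
  expect_equal(nrow(cohort_filter(missing11)), 0)
  all_missing <- mk(rep("MISSING", 20))
  expect_equal(nrow(cohort_filter(all_missing)), 0)
  shallow <- mk(c(rep("HET", 20)))
  shallow$mean_depth <- 4.9
  expect_equal(nrow(cohort_filter(shallow)), 0)
})

test_that("cohort filter agrees with a per-site oracle and is monotone in its thresholds", {
  sim <- sim_fixture(sites_per_chromosome = 500, seed = 29)
  sites <- read_vcf(sim$offspring_vcf)
  cfg <- filter_config()
  expect_identical(cohort_filter(sites, cfg)$pos,
                   sites$pos[oracle_cohort_keep(sites, cfg)])
  strict <- cohort_filter(sites, cfg)
  lax <- cohort_filter(sites, filter_config(maf_min = 0.01, max_missing = 0.2))
  expect_true(all(paste(strict$chrom, strict$pos) %in% paste(lax$chrom, lax$pos)))
})

test_that("filters preserve site order and return subsets", {
  sim <- sim_fixture(sites_per_chromosome = 300, seed = 31)
  sites <- read_vcf(sim$ancestor_a_vcf)
  for (out in list(hard_filter_sites(sites), snp_cluster_filter(sites),
                   cohort_filter(sites))) {
    key_in <- paste(sites$chrom, sites$pos)
    key_out <- paste(out$chrom, out$pos)
    expect_true(all(key_out %in% key_in))
    expect_false(is.unsorted(match(key_out, key_in)))
  }
})

test_that("substitutions partition into 4 transitions and 8 transversions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "TRANSITION"), 4)
  expect_equal(sum(cls == "TRANSVERSION"), 8)
  expect_identical(classify_substitution("A", "G"), "TRANSITION")
  expect_identical(classify_substitution("C", "A"), "TRANSVERSION")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A/C/G/T")
})

test_that("every simulated variant falls in exactly one class partition", {
  sim <- sim_fixture(sites_per_chromosome = 400, seed = 37)
  sites <- read_vcf(sim$ancestor_b_vcf)
  snp <- sites[sites$variant_class == "SNP", ]
  cls <- classify_substitution(snp$ref, snp$alt)
  expect_true(all(cls %in% c("TRANSITION", "TRANSVERSION")))
  expect_true(all(sites$variant_class %in% c("SNP", "INSERTION", "DELETION")))
  ins <- sites$variant_class == "INSERTION"
  del <- sites$variant_class == "DELETION"
  expect_true(all(xor(ins, del) | sites$variant_class == "SNP"))
})
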