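test_that("major-genotype calling follows the strict proportion rule", {
  # 14 of 18 is the smallest count exceeding 75%
  call14 <- call_major_genotype(c(rep("HOM_REF", 14), rep("HET", 4)), 0.75)
  expect_identical(call14$major_genotype, "HOM_REF")
  expect_equal(call14$major_proportion, 14 / 18)
  call13 <- call_major_genotype(c(rep("HOM_REF", 13), rep("HET", 5)), 0.75)
  expect_identical(call13$major_genotype, "NONE")
  # missing genotypes count in the denominator but never as candidates
  callm <- call_major_genotype(c(rep("HOM_ALT", 14), rep("MISSING", 4)), 0.75)
  expect_identical(callm$major_genotype, "HOM_ALT")
  expect_equal(callm$missing_fraction, 4 / 18)
  expect_identical(
    call_major_genotype(c(rep("HOM_ALT", 13), rep("MISSING", 5)), 0.75)$major_genotype,
    "NONE"
  )
  expect_error(call_major_genotype(character(0)), "non-empty")
})

test_that("ties for the most frequent genotype give NONE", {
  tie <- call_major_genotype(c(rep("HOM_REF", 3), rep("HOM_ALT", 3)), 0.4)
  expect_identical(tie$major_genotype, "NONE")
  expect_false(tie$is_homozygous_major)
})

test_that("the caller matches a brute-force counter on all small compositions", {
  for (n in 2:6) {
    grid <- expand.grid(hr = 0:n, het = 0:n, ha = 0:n)
    grid <- grid[rowSums(grid) <= n, ]
    for (i in seq_len(nrow(grid))) {
      g <- c(rep("HOM_REF", grid$hr[i]), rep("HET", grid$het[i]),
             rep("HOM_ALT", grid$ha[i]))
      g <- c(g, rep("MISSING", n - length(g)))
      for (th in c(0.5, 0.6, 0.75)) {
        expect_identical(call_major_genotype(g, th)$major_genotype,
                         oracle_major_genotype(g, th),
                         info = sprintf("n=%d comp=%s th=%.2f", n,
                                        paste(grid[i, ], collapse = "/"), th))
      }
    }
  }
})

test_that("informative sites require homozygous, differing majors in both cohorts", {
  calls <- function(major) {
    tibble::tibble(major_genotype = major,
                   is_homozygous_major = major %in% c("HOM_REF", "HOM_ALT"))
  }
  a <- calls(c("HOM_ALT", "HOM_ALT", "HOM_ALT", "NONE"))
  b <- calls(c("HOM_REF", "HET", "HOM_ALT", "HOM_REF"))
  expect_identical(detect_informative_sites(a, b), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(detect_informative_sites(a, b[1:2, ]), "misaligned")
})

test_that("offspring screening applies missingness, 60% rule and homozygosity", {
  expect_identical(
    screen_offspring_site(c(rep("HOM_ALT", 4), "HOM_REF", "MISSING")), "HOM_ALT")
  expect_identical(
    screen_offspring_site(c(rep("MISSING", 4), rep("HOM_ALT", 2))), "NONE")
  expect_identical(
    screen_offspring_site(c(rep("HET", 5), "HOM_REF")), "NONE")
  # 4 of 6 is the smallest count exceeding 60%
  expect_identical(
    screen_offspring_site(c(rep("HOM_REF", 3), rep("HOM_ALT", 2), "MISSING")), "NONE")
  expect_error(screen_offspring_site(character(0)), "non-empty")
})

test_that("origin assignment compares the offspring genotype to both ancestors", {
  expect_identical(assign_origin("HOM_ALT", "HOM_ALT", "HOM_REF"), "ANCESTOR_A")
  expect_identical(assign_origin("HOM_REF", "HOM_ALT", "HOM_REF"), "ANCESTOR_B")
  expect_error(assign_origin("HET", "HOM_ALT", "HOM_REF"), "homozygous")
  expect_error(assign_origin("HOM_REF", "HOM_ALT", "HOM_ALT"), "informative")
})

test_that("noise-free simulation is recovered perfectly", {
  sim <- simulate_dataset(sim_params(
    sites_per_chromosome = 1000, n_chromosomes = 2,
    fraction_informative = 0.5, admixture_proportion = 0.3,
    fixation = 1, missing_rate_genic = 0, missing_rate_intergenic = 0,
    seed = 41
  ))
  res <- assign_ancestry(read_vcf(sim$ancestor_a_vcf), read_vcf(sim$ancestor_b_vcf),
                         read_vcf(sim$offspring_vcf))
  truth <- dplyr::inner_join(res, sim$truth, by = c("chrom", "pos"))
  # detection equals the truth-table informative set exactly
  expect_identical(truth$informative, truth$true_origin != "UNINFORMATIVE")
  # every informative site is assigned, and to the true ancestor
  inf <- truth[truth$informative, ]
  expect_true(all(inf$origin %in% c("ANCESTOR_A", "ANCESTOR_B")))
  expect_identical(inf$origin, inf$true_origin)
})

test_that("attribution stays accurate under drift and genic missingness", {
  sim <- simulate_dataset(sim_params(
    sites_per_chromosome = 2000, n_chromosomes = 1,
    fixation = 0.95, missing_rate_genic = 0.05, missing_rate_intergenic = 0.7,
    seed = 43
  ))
  res <- assign_ancestry(read_vcf(sim$ancestor_a_vcf), read_vcf(sim$ancestor_b_vcf),
                         read_vcf(sim$offspring_vcf))
  truth <- dplyr::inner_join(res, sim$truth, by = c("chrom", "pos"))
  assigned <- truth[!is.na(truth$origin) & truth$origin != "UNASSIGNED", ]
  expect_gt(nrow(assigned), 200)
  expect_gte(mean(assigned$origin == assigned$true_origin), 0.95)
})

test_that("assigned sites partition the screened informative set", {
  sim <- sim_fixture(sites_per_chromosome = 400, seed = 47)
  res <- assign_ancestry(read_vcf(sim$ancestor_a_vcf), read_vcf(sim$ancestor_b_vcf),
                         read_vcf(sim$offspring_vcf))
  screened_informative <- sum(res$informative & res$offspring_gt != "NONE")
  expect_equal(sum(res$origin %in% c("ANCESTOR_A", "ANCESTOR_B", "UNASSIGNED")),
               screened_informative)
  # nothing heterozygous is ever assigned
  assigned <- res[!is.na(res$origin), ]
  expect_true(all(assigned$offspring_gt %in% c("HOM_REF", "HOM_ALT")))
  expect_true(all(assigned$major_a != "HET" & assigned$major_b != "HET"))
})

test_that("raising the ancestor threshold never enlarges the informative set", {
  sim <- sim_fixture(sites_per_chromosome = 400, seed = 53)
  a <- read_vcf(sim$ancestor_a_vcf)
  b <- read_vcf(sim$ancestor_b_vcf)
  sets <- lapply(c(0.55, 0.65, 0.75, 0.85, 0.95), function(th) {
    which(detect_informative_sites(call_major_genotypes(a$gt, th),
                                   call_major_genotypes(b$gt, th)))
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})
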