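# Genotype/sample IO, MAF, HWE exact test, and QC filtering.

test_that("GT parsing converts diploid calls to alt-allele counts", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "./."), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0|1", "1|1", "0/0", "0/1"), collapse = "\t"),
    paste(c("1", "300", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0/2", "0/0"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_warning(gm <- read_genotypes(f, "GT"), "multi-allelic")
  expect_equal(gm$variants$id, c("rs1", "rs2"))
  expect_equal(unname(gm$dosage["rs1", ]), c(0, 1, 2, NA))
  expect_equal(unname(gm$dosage["rs2", ]), c(1, 2, 0, 1))
  expect_error(suppressWarnings(read_genotypes(f, "DS")), "DS")
})

test_that("VCF round-trip via the package writer preserves dosages", {
  cfg <- sim_config(group_sizes = rep(10, 5), n_null_variants = 20,
                    age_means = rep(9, 5), dosage_noise_sd = 0.2, seed = 4)
  sim <- simulate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, f)
  back <- read_genotypes(f, "DS")
  expect_equal(back$dosage, sim$genotypes$dosage, tolerance = 1e-3)
  expect_identical(back$variants$id, sim$genotypes$variants$id)

  # hard calls round-trip through GT exactly
  cfg$dosage_noise_sd <- 0
  sim2 <- simulate_cohort(cfg)
  write_vcf(sim2$genotypes, f)
  back2 <- read_genotypes(f, "GT")
  expect_equal(back2$dosage, sim2$genotypes$dosage)
})

test_that("minor_allele_frequency folds and handles missing data", {
  expect_equal(minor_allele_frequency(c(0, 1, 2, 2)), 0.375)
  expect_equal(minor_allele_frequency(c(2, 2, 2, 2)), 0)
  expect_equal(minor_allele_frequency(c(0, 1, 1, 0, 2, 0, 1, 1)), 0.375)
  expect_equal(minor_allele_frequency(c(0, 1, NA, NA)), 0.25)
  expect_error(minor_allele_frequency(c(NA_real_, NA_real_)), "missing")
  # allele-relabeling invariance on random vectors
  set.seed(9)
  for (i in 1:25) {
    d <- sample(0:2, 40, replace = TRUE)
    expect_equal(minor_allele_frequency(d), minor_allele_frequency(2 - d))
  }
})

test_that("HWE exact test matches hand cases and the recurrence oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_equal(hwe_exact_test(3, 1, 3), hwe_oracle(3, 1, 3))
  expect_error(hwe_exact_test(-1, 2, 3), ">= 0")
  # all tables up to n = 20 against the independent recurrence
  for (n in 1:20) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                   tolerance = 1e-12)
    }
  }
})

test_that("apply_qc drops samples first, then variants, with reasons", {
  # 10 samples; sample T010 has 6% missing (3/50 variants). Variant v004 has
  # one minor allele among the other nine samples: with T010 present its MAF
  # is 1/20 = 0.050 (below the 0.055 gate), without T010 it is 1/18 = 0.056
  # (above). The fixed order — samples first — must therefore retain v004.
  set.seed(21)
  nv <- 50
  dos <- matrix(rbinom(nv * 10, 2, 0.3), nv, 10)
  dos[1:3, 10] <- NA                              # 6% missing for sample 10
  dos[4, ] <- c(1, rep(0, 9))
  st <- tiny_sample_table(K = 5, n_per = 2)
  gm <- tiny_genotypes(dos)
  res <- apply_qc(gm, st, qc_thresholds(maf_min = 0.055))
  expect_true("T010" %in% res$report$item[res$report$reason == "missingness"])
  expect_false("T010" %in% res$genotypes$samples)
  expect_true("v004" %in% res$genotypes$variants$id)
  expect_false("v004" %in% res$report$item)

  # call-rate removal reason at the default 95% gate
  dos2 <- matrix(rbinom(25 * 100, 2, 0.3), 25, 100)
  dos2[7, 1:6] <- NA                              # 94% call rate
  st2 <- tiny_sample_table(K = 5, n_per = 20)
  res2 <- apply_qc(tiny_genotypes(dos2), st2, qc_thresholds())
  rep7 <- res2$report[res2$report$item == "v007", ]
  expect_equal(rep7$reason, "call_rate")
  expect_false("v007" %in% res2$genotypes$variants$id)

  # variant passing all gates is retained
  expect_true("v001" %in% res2$genotypes$variants$id)
})

test_that("apply_qc is idempotent", {
  set.seed(22)
  dos <- matrix(rbinom(30 * 50, 2, runif(30, 0.02, 0.5)), 30, 50)
  dos[sample(length(dos), 40)] <- NA
  st <- tiny_sample_table(K = 5, n_per = 10)
  once <- apply_qc(tiny_genotypes(dos), st, qc_thresholds())
  twice <- apply_qc(once$genotypes, once$samples, qc_thresholds())
  expect_identical(twice$genotypes$dosage, once$genotypes$dosage)
  expect_identical(twice$samples, once$samples)
  expect_equal(nrow(twice$report), 0)
})

test_that("degenerate QC inputs fail loudly", {
  st <- tiny_sample_table(K = 2, n_per = 3)
  gm <- tiny_genotypes(matrix(0, 2, 6))          # monomorphic everywhere
  expect_error(apply_qc(gm, st), "survive QC")
  gm2 <- tiny_genotypes(matrix(1, 1, 6))
  st2 <- st
  st2$sample_id <- paste0("X", st2$sample_id)
  expect_error(apply_qc(gm2, st2), "shared")
})

test_that("sample table validation enforces the contract", {
  st <- tiny_sample_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(st, f)
  back <- read_sample_table(f)
  expect_equal(back$endophenotype, st$endophenotype)
  st_bad <- st
  st_bad$endophenotype[st$endophenotype == 5] <- 4
  st_bad$endophenotype[1] <- 5                   # category 5 now singleton
  expect_error(validate_sample_table(st_bad), ">= 2")
  st_dup <- st; st_dup$sample_id[2] <- st_dup$sample_id[1]
  expect_error(validate_sample_table(st_dup), "duplicate")
})
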