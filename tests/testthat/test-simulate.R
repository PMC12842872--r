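# Synthetic cohort generator.

test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_config(group_sizes = rep(20, 5), n_null_variants = 30,
                    age_means = rep(9, 5),
                    planted = list(planted_variant(seq(0.2, 0.4, 0.05),
                                                   "hit")),
                    null_maf_range = c(0.15, 0.5),
                    pc_confounding = c(0.02, rep(0, 9)), seed = 61)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(group_sizes = rep(20, 5),
                                   n_null_variants = 30,
                                   age_means = rep(9, 5), seed = 62))
  expect_false(identical(a$genotypes$dosage[1:30, ], c2$genotypes$dosage))
})

test_that("generated dosages match the generative frequencies", {
  cfg <- sim_config(n_null_variants = 2000, seed = 63)
  sim <- simulate_cohort(cfg)
  n2 <- 2 * sum(cfg$group_sizes)
  f_hat <- rowMeans(sim$genotypes$dosage[1:2000, ]) / 2
  f_true <- sim$truth$f1[1:2000]
  se <- sqrt(f_true * (1 - f_true) / n2)
  expect_gt(mean(abs(f_hat - f_true) <= 3 * se), 0.99 - 0.02)
  expect_lt(mean(f_hat - f_true), 0.005)          # no systematic bias
})

test_that("a planted gradient reproduces the intended delta-MAF", {
  cfg <- sim_config(
    n_null_variants = 0,
    planted = rep(list(planted_variant(c(0.25, 0.25, 0.25, 0.37, 0.37),
                                       "p1")), 1),
    seed = 64)
  cfg$planted[[1]]$label <- "p1"
  sim <- simulate_cohort(cfg)
  d <- sim$genotypes$dosage[1, ]
  g <- sim$samples$endophenotype
  f4 <- mean(d[g == 4]) / 2
  f1 <- mean(d[g == 1]) / 2
  se <- sqrt(0.37 * 0.63 / (2 * 163) + 0.25 * 0.75 / (2 * 171))
  expect_lt(abs((f4 - f1) - 0.12), 3 * se)
})

test_that("group structure, ages, and covariates follow the config", {
  cfg <- sim_config(seed = 65)
  sim <- simulate_cohort(cfg)
  expect_equal(as.integer(table(sim$samples$endophenotype)),
               c(171, 154, 168, 163, 177))
  age_means <- tapply(sim$samples$age, sim$samples$endophenotype, mean)
  expect_true(all(diff(age_means) > 0))           # monotone age gradient
  expect_equal(as.numeric(age_means), c(6.96, 7.87, 9.04, 9.87, 10.88),
               tolerance = 0.2)
  expect_true(all(sim$samples$sex %in% 0:1))
  expect_equal(mean(sim$samples$pc3), 0, tolerance = 0.15)
})

test_that("PC confounding shifts allele frequencies and inflates the
           unadjusted scan", {
  cfg <- sim_config(group_sizes = rep(60, 5), age_means = rep(9, 5),
                    n_null_variants = 300, null_maf_range = c(0.25, 0.5),
                    pc_confounding = c(0.08, rep(0, 9)), seed = 66)
  sim <- simulate_cohort(cfg)
  # dosage correlates with pc1 by construction
  cors <- apply(sim$genotypes$dosage[1:300, ], 1,
                function(d) cor(d, sim$samples$pc1))
  expect_gt(mean(cors), 0.05)
  # a phenotype built from the same PC makes the unadjusted test inflate
  st2 <- sim$samples
  st2$endophenotype <- as.integer(cut(st2$pc1, quantile(st2$pc1, 0:5 / 5),
                                      include.lowest = TRUE))
  sc_raw <- genome_scan(sim$genotypes, st2, covariates = character(0),
                        contrasts = "none", progress_every = 0)
  sc_adj <- genome_scan(sim$genotypes, st2, contrasts = "none",
                        progress_every = 0)
  infl_raw <- mean(sc_raw$records$p < 0.05, na.rm = TRUE)
  infl_adj <- mean(sc_adj$records$p < 0.05, na.rm = TRUE)
  expect_gt(infl_raw, 0.10)                       # clearly inflated
  expect_lt(infl_adj, 0.10)                       # PC adjustment repairs it
})

test_that("cohort pairs share truth and support attenuation", {
  mk <- function(seed) sim_config(
    group_sizes = rep(30, 5), age_means = rep(9, 5), n_null_variants = 10,
    planted = list(planted_variant(c(0.2, 0.2, 0.2, 0.35, 0.35), "hit")),
    seed = seed)
  pair <- simulate_cohort_pair(mk(67), mk(68), shared_truth = TRUE)
  expect_identical(pair$discovery$truth, pair$replication$truth)
  expect_false(identical(pair$discovery$genotypes$dosage,
                         pair$replication$genotypes$dosage))
  # attenuation 0 flattens the planted pattern in the replication cohort
  pair0 <- simulate_cohort_pair(mk(67), mk(68), shared_truth = TRUE,
                                attenuation = 0)
  frep <- unlist(pair0$replication$truth[11, paste0("f", 1:5)])
  expect_equal(unname(frep), rep(mean(c(0.2, 0.2, 0.2, 0.35, 0.35)), 5),
               tolerance = 1e-12)
  # replication defaults carry the stated group sizes
  cfgR <- sim_config_replication(n_null_variants = 5, seed = 1)
  expect_equal(cfgR$group_sizes, c(207, 205, 204, 207, 207))
  expect_error(simulate_cohort_pair(mk(1), sim_config(n_null_variants = 3,
                                                      seed = 2)),
               "variant list")
})

test_that("dosages are HWE-consistent: valid exact p at every threshold
           and uniform after randomization", {
  cfg <- sim_config(n_null_variants = 2000, seed = 69)
  sim <- simulate_cohort(cfg)
  p_exact <- apply(sim$genotypes$dosage, 1, function(d) {
    cc <- table(factor(round(d), 0:2))
    hwe_exact_test(cc[1], cc[2], cc[3])
  })
  for (t in c(0.01, 0.05, 0.1, 0.5)) {
    se <- sqrt(t * (1 - t) / 2000)
    expect_lte(mean(p_exact <= t), t + 3 * se)    # valid, conservative
    expect_gte(mean(p_exact <= t), t - 5 * se)    # but not degenerate
  }
  # randomized exact p-values are Uniform(0,1) under H0
  set.seed(70)
  p_rand <- apply(sim$genotypes$dosage, 1, function(d) {
    cc <- as.integer(table(factor(round(d), 0:2)))
    p_le <- hwe_exact_test(cc[1], cc[2], cc[3])
    # probability of strictly more-probable configurations
    n <- sum(cc); nA <- 2 * cc[1] + cc[2]
    hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
      lfactorial(n - (nA + hets) / 2) + hets * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    pr <- exp(lp)
    p_obs <- pr[match(cc[2], hets)]
    p_lt <- p_le - sum(pr[abs(pr - p_obs) <= p_obs * 1e-9])
    p_lt + runif(1) * (p_le - p_lt)
  })
  expect_gt(ks.test(p_rand, "punif")$p.value, 0.01)
})

test_that("excessive clamping under confounding warns loudly", {
  cfg <- sim_config(group_sizes = rep(20, 5), age_means = rep(9, 5),
                    n_null_variants = 50, null_maf_range = c(0.05, 0.1),
                    pc_confounding = 0.3, seed = 71)
  expect_warning(simulate_cohort(cfg), "clamped")
})
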