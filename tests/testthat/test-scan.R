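# ANCOVA partial F, adjusted means, Tukey contrasts, trend test, scan.

test_that("zero between-group variance gives F = 0, p = 1", {
  st <- tiny_sample_table(K = 5, n_per = 4)
  y <- rep(c(0, 1, 1, 2), 5)                     # identical group multisets
  rec <- fit_ancova(y, st, covariates = character(0))
  expect_equal(rec$F, 0)
  expect_equal(rec$p, 1)
})

test_that("two groups without covariates reproduce the pooled t-test", {
  set.seed(31)
  st <- tiny_sample_table(K = 2, n_per = 12)
  y <- rbinom(24, 2, 0.4)
  y[1] <- 2                                      # ensure non-monomorphic
  rec <- fit_ancova(y, st, covariates = character(0))
  tt <- t.test(y[st$endophenotype == 1], y[st$endophenotype == 2],
               var.equal = TRUE)
  expect_equal(rec$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(rec$p, tt$p.value, tolerance = 1e-12)
})

test_that("partial F and p match the explicit normal-equation oracle", {
  set.seed(32)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n_per <- sample(3:8, 1)
    st <- tiny_sample_table(K = K, n_per = n_per, seed = 1000 + i)
    covars <- sample(c("age", "sex", "pc1"), sample(0:3, 1))
    y <- rnorm(K * n_per) + 0.5 * st$endophenotype
    rec <- fit_ancova(y, st, covariates = covars)
    orc <- partialF_oracle(y, st$endophenotype,
                           if (length(covars))
                             as.matrix(st[, covars, drop = FALSE]))
    expect_equal(rec$F, orc$F, tolerance = 1e-10)
    expect_equal(rec$p, orc$p, tolerance = 1e-10)
    expect_identical(c(rec$df1, rec$df2), c(orc$df1, orc$df2))
  }
})

test_that("ANCOVA with no covariates is textbook one-way ANOVA", {
  set.seed(33)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    sizes <- sample(3:9, K, replace = TRUE)
    g <- rep(seq_len(K), sizes)
    y <- rnorm(sum(sizes))
    st <- data.frame(sample_id = as.character(seq_along(g)),
                     endophenotype = g, age = 0, sex = 0)
    rec <- fit_ancova(y, st, covariates = character(0))
    # explicit SSB/SSW formulas
    gm <- tapply(y, g, mean)
    ssb <- sum(sizes * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    Fref <- (ssb / (K - 1)) / (ssw / (length(y) - K))
    expect_equal(rec$F, Fref, tolerance = 1e-10)
    # adjusted means with no covariates are the raw group means
    expect_equal(unname(rec$adj_means), as.numeric(gm), tolerance = 1e-12)
  }
})

test_that("F is invariant under affine transformation of the dosage", {
  set.seed(34)
  st <- tiny_sample_table(K = 5, n_per = 10)
  y <- rbinom(50, 2, 0.3) + 0.01 * seq_len(50)
  r1 <- fit_ancova(y, st)
  r2 <- fit_ancova(1.7 * y - 0.4, st)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("degenerate designs are reported, not silently fit", {
  st <- tiny_sample_table(K = 3, n_per = 5)
  y <- rep(1, 15)
  rec <- fit_ancova(y, st)
  expect_true(is.na(rec$F))
  expect_equal(rec$reason, "monomorphic")

  st2 <- st
  st2$pc2 <- st2$pc1                              # collinear covariates
  y2 <- rnorm(15)
  expect_error(fit_ancova(y2, st2, covariates = c("age", "pc1", "pc2")),
               "collinear")

  y3 <- rnorm(15)
  y3[st$endophenotype == 2] <- NA                 # group emptied
  expect_error(fit_ancova(y3, st), "emptied")
})

test_that("Tukey contrasts reduce to known cases", {
  # identical adjusted means -> all p_adj = 1
  ct <- tukey_hsd(rep(1.5, 4), mse = 0.3, group_n = rep(10, 4), df2 = 36)
  expect_equal(ct$p_adj, rep(1, 6))
  expect_equal(nrow(ct), 6)

  # K = 2: single contrast equals the unadjusted two-sample t-test p
  set.seed(35)
  y <- rnorm(30) + rep(c(0, 0.8), each = 15)
  g <- rep(1:2, each = 15)
  st <- data.frame(sample_id = as.character(1:30), endophenotype = g,
                   age = 0, sex = 0)
  rec <- fit_ancova(y, st, covariates = character(0), contrasts = TRUE)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(rec$contrasts$p_adj, tt$p.value, tolerance = 1e-7)

  # one group shifted by 5 standard errors: its contrasts significant
  n <- c(20, 20, 20, 20, 20); mse <- 1
  se <- sqrt(mse * (1 / 20 + 1 / 20) / 2)
  means <- c(0, 0, 0, 0, 5 * se)
  ct2 <- tukey_hsd(means, mse, n, df2 = 95)
  hit <- ct2$group_a == "5" | ct2$group_b == "5"
  expect_true(all(ct2$p_adj[hit] < 0.05))
  expect_true(all(ct2$p_adj[!hit] > 0.05))
  expect_error(tukey_hsd(means, mse, c(1, 20, 20, 20, 20), 95), "n >= 2")
})

test_that("covariate-free ANCOVA contrasts match base TukeyHSD", {
  set.seed(36)
  for (i in 1:10) {
    sizes <- sample(8:15, 4, replace = TRUE)
    g <- factor(rep(1:4, sizes))
    y <- rnorm(sum(sizes)) + rep(runif(4, 0, 1), sizes)
    st <- data.frame(sample_id = as.character(seq_along(g)),
                     endophenotype = as.integer(g), age = 0, sex = 0)
    rec <- fit_ancova(y, st, covariates = character(0), contrasts = TRUE)
    ref <- TukeyHSD(aov(y ~ g))$g
    key <- paste(rec$contrasts$group_a, rec$contrasts$group_b, sep = "-")
    expect_equal(rec$contrasts$p_adj, unname(ref[key, "p adj"]),
                 tolerance = 1e-7)
    expect_equal(rec$contrasts$diff, unname(ref[key, "diff"]),
                 tolerance = 1e-10)
  }
})

test_that("genome_scan is complete and robust to bad variants", {
  set.seed(37)
  cfg <- sim_config(group_sizes = rep(30, 5), n_null_variants = 40,
                    age_means = seq(7, 11, 1), seed = 37)
  sim <- simulate_cohort(cfg)
  sim$genotypes$dosage[3, ] <- 0                  # monomorphic row
  sc <- genome_scan(sim$genotypes, sim$samples, contrasts = "none",
                    progress_every = 0)
  expect_equal(nrow(sc$records), 40)
  expect_true(is.na(sc$records$p[3]))
  expect_match(sc$records$reason[3], "monomorphic")
  expect_false(any(is.na(sc$records$p[-3])))
  # flagged mode computes contrasts only for genome-wide hits
  sc2 <- genome_scan(sim$genotypes, sim$samples, alpha_gw = 0.5,
                     contrasts = "flagged", progress_every = 0)
  expect_setequal(unique(sc2$contrasts$variant),
                  sc2$records$variant[sc2$records$gw_flag])
  # per-variant n equals the sample count (no missingness here)
  expect_true(all(sc$records$n[-3] == 150))
})

test_that("severity trend detects exact and planted gradients", {
  st <- tiny_sample_table(K = 5, n_per = 6)
  y <- as.numeric(st$endophenotype)               # y = score exactly
  tr <- severity_trend(y, st, covariates = character(0))
  expect_equal(tr$slope, 1, tolerance = 1e-12)
  expect_lt(tr$p, 1e-200)
  expect_error(severity_trend(y, st, score = rep(1, 30)), "constant")
  # continuous per-sample score is accepted
  tr2 <- severity_trend(y, st, score = st$endophenotype + rnorm(30, 0, 0.1),
                        covariates = character(0))
  expect_lt(tr2$p, 1e-6)
})

test_that("scan output files have the documented shapes", {
  cfg <- sim_config(group_sizes = rep(10, 5), n_null_variants = 8,
                    age_means = rep(9, 5), seed = 38)
  sim <- simulate_cohort(cfg)
  sc <- genome_scan(sim$genotypes, sim$samples, contrasts = "all",
                    progress_every = 0, covariates = c("age", "sex"))
  pre <- withr::local_tempfile()
  write_scan(sc, pre)
  recs <- read.delim(paste0(pre, "_scan.tsv"))
  expect_true(all(c("variant", "chrom", "pos", "n", "F", "df1", "df2", "p",
                    "gw_flag", paste0("adj_mean_", 1:5)) %in% names(recs)))
  man <- read.delim(paste0(pre, "_manhattan.tsv"))
  expect_identical(names(man), c("chrom", "pos", "p"))
})
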