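# Synthetic two-cohort generator: group-structured allele frequencies,
# age/sex/ancestry-PC covariates, optional PC confounding of allele
# frequency, and an AR(1) block generator for LD structure.

#' Planted variant description
#'
#' A variant whose minor-allele frequency differs by endophenotype group —
#' the alternative the scan is built to detect.
#'
#' @param group_mafs K allele frequencies in (0, 1), one per group.
#' @param label variant id used in the output.
#' @export
planted_variant <- function(group_mafs, label) {
  if (any(group_mafs <= 0 | group_mafs >= 1))
    stop("planted frequencies must lie in (0, 1)")
  list(group_mafs = group_mafs, label = label)
}

#' Simulation configuration
#'
#' Defaults emulate the discovery cohort of a five-group pediatric asthma
#' endophenotype design: group sizes 171/154/168/163/177, a monotone age
#' gradient across severity groups (means 6.96-10.88 years), roughly 40%
#' female, and 10 standard-normal ancestry PCs. `pc_confounding` adds a
#' per-PC slope on the latent allele frequency so that population structure
#' genuinely confounds the scan unless PCs are adjusted for.
#'
#' @param group_sizes K group sizes.
#' @param n_null_variants number of null variants (shared frequency across
#'   groups, drawn Uniform over `null_maf_range`).
#' @param planted list of [planted_variant()] objects.
#' @param age_means,age_sd per-group age means and common SD (years).
#' @param sex_frac probability of sex code 1.
#' @param n_pcs number of ancestry PCs.
#' @param pc_confounding numeric vector (recycled to `n_pcs`) of
#'   allele-frequency slopes per PC unit.
#' @param null_maf_range range for null-variant frequencies.
#' @param dosage_noise_sd optional truncated-Gaussian noise added to hard
#'   genotype calls, mimicking imputation uncertainty (0 = hard calls).
#' @param seed RNG seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = c(171, 154, 168, 163, 177),
                       n_null_variants = 1000,
                       planted = list(),
                       age_means = c(6.96, 7.87, 9.04, 9.87, 10.88),
                       age_sd = 1.8,
                       sex_frac = 0.40,
                       n_pcs = 10,
                       pc_confounding = 0,
                       null_maf_range = c(0.05, 0.5),
                       dosage_noise_sd = 0,
                       seed = 1) {
  if (any(group_sizes < 2)) stop("all group sizes must be >= 2")
  if (length(age_means) != length(group_sizes))
    stop("age_means must match group_sizes in length")
  for (pv in planted)
    if (length(pv$group_mafs) != length(group_sizes))
      stop("planted variant '", pv$label, "' needs one frequency per group")
  structure(list(group_sizes = group_sizes,
                 n_null_variants = n_null_variants, planted = planted,
                 age_means = age_means, age_sd = age_sd,
                 sex_frac = sex_frac, n_pcs = n_pcs,
                 pc_confounding = rep_len(pc_confounding, n_pcs),
                 null_maf_range = null_maf_range,
                 dosage_noise_sd = dosage_noise_sd, seed = seed),
            class = "sim_config")
}

#' Replication-cohort configuration defaults
#'
#' Convenience wrapper with the replication cohort's group sizes
#' (207/205/204/207/207) and age gradient.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_replication <- function(...) {
  args <- list(group_sizes = c(207, 205, 204, 207, 207),
               age_means = c(8.25, 8.66, 9.15, 9.82, 9.95))
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

#' Read a simulation configuration from JSON
#' @param path JSON file; fields mirror the arguments of [sim_config()],
#'   with `planted` a list of `{group_mafs, label}` objects.
#' @export
read_sim_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(js$planted)) {
    pl <- js$planted
    js$planted <- if (is.data.frame(pl)) {
      lapply(seq_len(nrow(pl)),
             function(i) planted_variant(unlist(pl$group_mafs[i]),
                                         pl$label[i]))
    } else {
      lapply(pl, function(p) planted_variant(unlist(p$group_mafs), p$label))
    }
  }
  do.call(sim_config, js)
}

#' Simulate a synthetic cohort
#'
#' Per sample: group label from `group_sizes`, age ~ Normal(group mean, sd),
#' sex ~ Bernoulli(`sex_frac`), PCs ~ standard Normal. Per variant and
#' sample, the allele frequency is the group's base frequency plus the PC
#' confounding contribution (clamped into (0, 1) with a warning if more than
#' 1% of draws clamp), and the genotype is Binomial(2, f). Null variants
#' share one frequency across groups.
#'
#' @param cfg A [sim_config()] object.
#' @param null_f optional vector overriding the null-variant frequencies
#'   (used to share generative truth across a cohort pair).
#' @return List `genotypes` (a `genotype_matrix`), `samples` (sample table),
#'   `truth` (data.frame of generative frequencies per variant per group).
#' @export
simulate_cohort <- function(cfg, null_f = NULL) {
  set.seed(cfg$seed)
  # null frequencies are the first draw so a cohort pair can share them
  f0 <- if (cfg$n_null_variants > 0) {
    stats::runif(cfg$n_null_variants, cfg$null_maf_range[1],
                 cfg$null_maf_range[2])
  } else numeric(0)
  if (!is.null(null_f)) {
    stopifnot(length(null_f) == cfg$n_null_variants)
    f0 <- null_f
  }
  K <- length(cfg$group_sizes)
  n <- sum(cfg$group_sizes)
  grp <- rep(seq_len(K), cfg$group_sizes)
  st <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    endophenotype = grp,
    age = stats::rnorm(n, cfg$age_means[grp], cfg$age_sd),
    sex = stats::rbinom(n, 1, cfg$sex_frac),
    stringsAsFactors = FALSE)
  pcs <- matrix(stats::rnorm(n * cfg$n_pcs), n, cfg$n_pcs)
  colnames(pcs) <- paste0("pc", seq_len(cfg$n_pcs))
  st <- cbind(st, pcs)
  pc_shift <- as.vector(pcs %*% cfg$pc_confounding)

  n_pl <- length(cfg$planted)
  nv <- cfg$n_null_variants + n_pl
  base_f <- matrix(NA_real_, nv, K)
  labels <- character(nv)
  types <- character(nv)
  if (cfg$n_null_variants > 0) {
    base_f[seq_len(cfg$n_null_variants), ] <- f0
    labels[seq_len(cfg$n_null_variants)] <-
      sprintf("null%05d", seq_len(cfg$n_null_variants))
    types[seq_len(cfg$n_null_variants)] <- "null"
  }
  for (j in seq_along(cfg$planted)) {
    i <- cfg$n_null_variants + j
    base_f[i, ] <- cfg$planted[[j]]$group_mafs
    labels[i] <- cfg$planted[[j]]$label
    types[i] <- "planted"
  }
  dosage <- matrix(NA_real_, nv, n)
  n_clamped <- 0
  for (i in seq_len(nv)) {
    f <- base_f[i, grp] + pc_shift
    cl <- f <= 0.001 | f >= 0.999
    n_clamped <- n_clamped + sum(cl)
    f <- pmin(pmax(f, 0.001), 0.999)
    dosage[i, ] <- stats::rbinom(n, 2, f)
  }
  if (n_clamped > 0.01 * nv * n)
    warning(sprintf(
      "PC confounding clamped %.1f%% of allele-frequency draws",
      100 * n_clamped / (nv * n)))
  if (cfg$dosage_noise_sd > 0) {
    noise <- stats::rnorm(length(dosage), 0, cfg$dosage_noise_sd)
    dosage <- pmin(pmax(dosage + noise, 0), 2)
  }
  variants <- data.frame(id = labels, chrom = "1",
                         pos = 10000L * seq_len(nv),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  truth <- data.frame(id = labels, type = types,
                      matrix(base_f, nv, K,
                             dimnames = list(NULL, paste0("f", seq_len(K)))),
                      stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(variants, st$sample_id, dosage),
       samples = st, truth = truth)
}

#' Simulate a discovery/replication cohort pair
#'
#' Both cohorts carry the same variant list. With `shared_truth`, null
#' frequencies and planted group-frequency patterns are common to both
#' cohorts, with the planted between-group deviations optionally shrunk
#' toward their mean by `attenuation` (1 = identical effects, 0 = the
#' replication cohort is null for the planted variants).
#'
#' @param cfg_discovery,cfg_replication [sim_config()] objects with matching
#'   variant lists (same `n_null_variants` and planted labels).
#' @param shared_truth share generative frequencies across cohorts.
#' @param attenuation effect attenuation factor in the replication cohort.
#' @return List `discovery`, `replication` (each as [simulate_cohort()]).
#' @export
simulate_cohort_pair <- function(cfg_discovery, cfg_replication,
                                 shared_truth = TRUE, attenuation = 1) {
  lab_d <- vapply(cfg_discovery$planted, `[[`, "", "label")
  lab_r <- vapply(cfg_replication$planted, `[[`, "", "label")
  if (cfg_discovery$n_null_variants != cfg_replication$n_null_variants ||
      !identical(lab_d, lab_r))
    stop("discovery and replication configs must share one variant list")
  disc <- simulate_cohort(cfg_discovery)
  if (shared_truth) {
    K <- length(cfg_replication$group_sizes)
    cfg_replication$planted <- lapply(cfg_replication$planted, function(pv) {
      f_d <- cfg_discovery$planted[[match(pv$label, lab_d)]]$group_mafs
      m <- mean(f_d)
      planted_variant(pmin(pmax(m + attenuation * (f_d - m), 0.001), 0.999),
                      pv$label)
    })
    # share the discovery cohort's null frequencies
    null_f <- disc$truth$f1[disc$truth$type == "null"]
    rep_cohort <- simulate_cohort(cfg_replication, null_f = null_f)
  } else {
    rep_cohort <- simulate_cohort(cfg_replication)
  }
  list(discovery = disc, replication = rep_cohort)
}

#' Simulate a cohort with AR(1) LD blocks
#'
#' Generates correlated dosages to exercise LD clumping: within each block,
#' two latent haplotype-level Gaussian AR(1) chains (lag correlation `rho`)
#' are thresholded at the allele-frequency quantile, so adjacent variants
#' are in LD while blocks are independent. This is a device for testing
#' clumping, not a model of human LD.
#'
#' @param n_samples number of samples.
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param rho latent AR(1) lag correlation in (0, 1).
#' @param maf allele frequency (shared by all variants).
#' @param seed RNG seed.
#' @return A `genotype_matrix` with block structure encoded in variant ids
#'   (`b<block>v<rank>`).
#' @export
simulate_ld_blocks <- function(n_samples, n_blocks, block_size, rho = 0.9,
                               maf = 0.3, seed = 1) {
  set.seed(seed)
  nv <- n_blocks * block_size
  thr <- stats::qnorm(maf)
  dosage <- matrix(0, nv, n_samples)
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1) * block_size + seq_len(block_size)
    for (hap in 1:2) {
      z <- matrix(NA_real_, block_size, n_samples)
      z[1, ] <- stats::rnorm(n_samples)
      if (block_size > 1)
        for (v in 2:block_size)
          z[v, ] <- rho * z[v - 1, ] +
            sqrt(1 - rho^2) * stats::rnorm(n_samples)
      dosage[rows, ] <- dosage[rows, ] + (z < thr)
    }
  }
  variants <- data.frame(
    id = paste0("b", rep(seq_len(n_blocks), each = block_size),
                "v", rep(seq_len(block_size), n_blocks)),
    chrom = "1", pos = 10000L * seq_len(nv), ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  genotype_matrix(variants, sprintf("S%04d", seq_len(n_samples)), dosage)
}
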