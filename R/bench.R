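# Simulation benchmark (ANCOVA-F vs one-vs-rest-Bonferroni vs trend),
# discovery-to-replication harness, and significance accounting.

#' Define a benchmark scenario
#'
#' One generative condition for [run_bench()]: a single variant with the
#' stated per-group allele frequencies, drawn repeatedly together with fresh
#' covariates at the stated group sizes.
#'
#' @param label scenario name.
#' @param group_mafs K allele frequencies (equal values = null scenario).
#' @param group_sizes K group sizes (default: discovery-cohort sizes).
#' @param cfg base [sim_config()] supplying covariate structure.
#' @export
bench_scenario <- function(label, group_mafs,
                           group_sizes = c(171, 154, 168, 163, 177),
                           cfg = sim_config(group_sizes = group_sizes,
                                            n_null_variants = 0)) {
  cfg$group_sizes <- group_sizes
  list(label = label, group_mafs = group_mafs, cfg = cfg)
}

#' Paired power / type-I-error benchmark
#'
#' For each scenario and replicate, one cohort (covariates + a single
#' variant with the scenario's group frequencies) is simulated and the same
#' data are handed to every method: the ANCOVA partial F (reject when
#' `p <= alpha`), K one-vs-rest logistic fits with within-variant Bonferroni
#' (reject when any `p <= alpha / K`), and the severity-trend regression
#' (reject when `p <= alpha`). Because methods are paired per replicate,
#' comparisons can use McNemar-style discordant counts; the per-replicate
#' rejection indicators are returned as an attribute.
#'
#' @param scenarios list of [bench_scenario()] objects.
#' @param n_reps replicates per scenario (>= 100).
#' @param alpha rejection threshold (default 1e-4, so modest replicate
#'   counts resolve power; the genome-wide 5e-8 is for real scans).
#' @param seed RNG seed.
#' @param covariates covariate columns to adjust for.
#' @return data.frame of class `bench_result`: one row per scenario x
#'   method, columns `scenario method rate mc_se n_reps alpha`; attribute
#'   `indicators` holds the per-replicate rejection matrix per scenario.
#' @export
run_bench <- function(scenarios, n_reps = 1000, alpha = 1e-4, seed = 1,
                      covariates = default_covariates()) {
  if (n_reps < 100) stop("need n_reps >= 100 for stable rates")
  methods <- c("ancova", "ovr_bonferroni", "trend")
  out <- list()
  indicators <- list()
  for (sc in scenarios) {
    K <- length(sc$group_mafs)
    rej <- matrix(FALSE, n_reps, length(methods),
                  dimnames = list(NULL, methods))
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- sc$cfg
      cfg$n_null_variants <- 0
      cfg$planted <- list(planted_variant(sc$group_mafs, "v"))
      cfg$seed <- seeds[r]
      sim <- simulate_cohort(cfg)
      y <- sim$genotypes$dosage[1, ]
      st <- sim$samples
      rec <- tryCatch(fit_ancova(y, st, covariates),
                      error = function(e) list(p = NA))
      rej[r, "ancova"] <- !is.na(rec$p) && rec$p <= alpha
      p_ovr <- vapply(seq_len(K), function(k) {
        r2 <- tryCatch(
          fit_ovr(as.integer(st$endophenotype == k), y, st, covariates),
          error = function(e) list(p = NA_real_))
        r2$p %||% NA_real_
      }, numeric(1))
      rej[r, "ovr_bonferroni"] <- any(p_ovr <= alpha / K, na.rm = TRUE)
      tr <- tryCatch(severity_trend(y, st, covariates = covariates),
                     error = function(e) list(p = NA))
      rej[r, "trend"] <- !is.na(tr$p) && tr$p <= alpha
    }
    rate <- colMeans(rej)
    out[[sc$label]] <- data.frame(
      scenario = sc$label, method = methods, rate = unname(rate),
      mc_se = sqrt(unname(rate) * (1 - unname(rate)) / n_reps),
      n_reps = n_reps, alpha = alpha, stringsAsFactors = FALSE)
    indicators[[sc$label]] <- rej
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "indicators") <- indicators
  class(res) <- c("bench_result", "data.frame")
  res
}

#' Discovery-to-replication harness
#'
#' Re-runs the ANCOVA (with Tukey contrasts) for each discovery hit in the
#' replication cohort, flags nominal replication (`p < alpha_rep`), compares
#' the Tukey-significant contrast sets, and appends the cross-cohort MAF
#' direction concordance.
#'
#' @param hits variant ids taken forward from the discovery scan.
#' @param disc,repl cohorts as `list(genotypes, samples)` (e.g. from
#'   [simulate_cohort()] or [apply_qc()]).
#' @param alpha_rep replication threshold (default 0.05).
#' @param alpha_contrast Tukey contrast threshold (default 0.05).
#' @param covariates covariate columns to adjust for.
#' @return data.frame of class `replication_report`: per variant the
#'   discovery and replication p, `nominal_replicated`, contrast counts and
#'   overlap, and `direction_concordant`; totals in attributes.
#' @export
replicate_hits <- function(hits, disc, repl, alpha_rep = 0.05,
                           alpha_contrast = 0.05,
                           covariates = default_covariates()) {
  rows <- lapply(hits, function(v) {
    base <- data.frame(variant = v, p_disc = NA_real_, p_rep = NA_real_,
                       nominal_replicated = NA, n_contrasts_disc = NA_integer_,
                       n_contrasts_rep = NA_integer_,
                       n_contrast_overlap = NA_integer_,
                       direction_concordant = NA, reason = NA_character_,
                       stringsAsFactors = FALSE)
    i_d <- match(v, disc$genotypes$variants$id)
    i_r <- match(v, repl$genotypes$variants$id)
    if (is.na(i_d)) { base$reason <- "absent_from_discovery"; return(base) }
    if (is.na(i_r)) { base$reason <- "absent_from_replication"; return(base) }
    fit1 <- fit_ancova(disc$genotypes$dosage[i_d, ], disc$samples,
                       covariates, contrasts = TRUE)
    fit2 <- fit_ancova(repl$genotypes$dosage[i_r, ], repl$samples,
                       covariates, contrasts = TRUE)
    sig <- function(f) {
      if (is.null(f$contrasts)) return(character(0))
      with(f$contrasts[f$contrasts$p_adj < alpha_contrast, , drop = FALSE],
           paste(group_a, group_b, sep = "-"))
    }
    s1 <- sig(fit1); s2 <- sig(fit2)
    base$p_disc <- fit1$p
    base$p_rep <- fit2$p
    base$nominal_replicated <- !is.na(fit2$p) && fit2$p < alpha_rep
    base$n_contrasts_disc <- length(s1)
    base$n_contrasts_rep <- length(s2)
    base$n_contrast_overlap <- length(intersect(s1, s2))
    md <- maf_table(disc$genotypes, disc$samples, v)
    mr <- maf_table(repl$genotypes, repl$samples, v)
    base$direction_concordant <-
      direction_concordance(md, mr)$concordant[1]
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "n_replicated") <- sum(out$nominal_replicated, na.rm = TRUE)
  attr(out, "n_concordant") <- sum(out$direction_concordant, na.rm = TRUE)
  class(out) <- c("replication_report", "data.frame")
  out
}

#' Count significant post-hoc contrasts
#'
#' Number of Tukey contrasts with `p_adj` below `alpha`, in total and per
#' variant.
#'
#' @param contrasts data.frame with columns `variant` and either `p_adj`
#'   (a contrast table from [genome_scan()]) or a logical `significant`
#'   column (an encoded published post-hoc table, which reports only which
#'   contrasts survived correction).
#' @param alpha significance threshold (default 0.05).
#' @return List `total` and `per_variant` (named integer vector).
#' @export
contrast_count <- function(contrasts, alpha = 0.05) {
  if (!nrow(contrasts))
    return(list(total = 0L, per_variant = integer(0)))
  sig <- if ("p_adj" %in% names(contrasts)) {
    !is.na(contrasts$p_adj) & contrasts$p_adj < alpha
  } else if ("significant" %in% names(contrasts)) {
    as.logical(contrasts$significant)
  } else stop("contrast table needs a p_adj or significant column")
  list(total = sum(sig),
       per_variant = vapply(split(sig, contrasts$variant), sum, integer(1)))
}
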