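# Per-variant ANCOVA scan: partial F for the endophenotype factor,
# covariate-adjusted group means, Tukey-Kramer post-hoc contrasts, and the
# ordinal severity-trend regression.

default_covariates <- function(n_pcs = 10) c("age", "sex", paste0("pc", seq_len(n_pcs)))

# Build the full and reduced design matrices once for a cohort.
# group: factor; covars: numeric matrix (may have 0 columns).
build_designs <- function(group, covars) {
  K <- nlevels(group)
  G <- stats::model.matrix(~group)          # intercept + K-1 indicators
  colnames(G) <- c("(Intercept)", paste0("group", levels(group)[-1]))
  X_full <- cbind(G, covars)
  X_red <- cbind(G[, 1, drop = FALSE], covars)
  list(full = X_full, red = X_red, K = K)
}

# Core least-squares engine shared by fit_ancova and genome_scan.
ancova_engine <- function(y, group, covars, check_rank = TRUE) {
  K <- nlevels(group)
  n <- length(y)
  p_cov <- ncol(covars)
  des <- build_designs(group, covars)
  if (check_rank) {
    qrX <- qr(des$full)
    if (qrX$rank < ncol(des$full)) {
      bad <- colnames(des$full)[qrX$pivot[(qrX$rank + 1):ncol(des$full)]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  fit_full <- stats::lm.fit(des$full, y)
  fit_red <- stats::lm.fit(des$red, y)
  sse_full <- sum(fit_full$residuals^2)
  sse_red <- sum(fit_red$residuals^2)
  df1 <- K - 1
  df2 <- n - K - p_cov
  mse <- sse_full / df2
  Fstat <- ((sse_red - sse_full) / df1) / mse
  beta <- fit_full$coefficients
  # least-squares means: group effect + covariates at their sample averages
  cov_part <- if (p_cov) sum(beta[(K + 1):(K + p_cov)] * colMeans(covars)) else 0
  eff <- c(0, beta[2:K])
  adj_means <- beta[1] + eff + cov_part
  names(adj_means) <- levels(group)
  # unit covariance (per unit error variance) of the K-1 group-effect
  # coefficients; group 1 is the reference with effect fixed at 0
  XtXinv <- chol2inv(chol(crossprod(des$full)))
  vcov_unit <- matrix(0, K, K)
  vcov_unit[2:K, 2:K] <- XtXinv[2:K, 2:K]
  list(n_used = n, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       adj_means = adj_means, mse = mse,
       group_n = as.integer(table(group)), vcov_unit = vcov_unit)
}

#' Fit the per-variant ANCOVA model
#'
#' Reverse-regression ANCOVA: genotype dosage as response, the endophenotype
#' category as a K-level factor, and continuous covariates (age, sex,
#' ancestry PCs by default). The factor is tested with the partial
#' (model-comparison) F statistic
#' `F = [(SSE_red - SSE_full)/(K-1)] / [SSE_full/df2]`,
#' where the reduced model drops the factor. Samples missing the dosage are
#' dropped (per-variant complete-case analysis). Adjusted group means are
#' least-squares means evaluated at the sample-average covariate values.
#'
#' @param y dosage vector, one value per row of `st` (NA = missing).
#' @param st sample table (see [read_sample_table()]).
#' @param covariates character vector of covariate column names in `st`;
#'   use `character(0)` for an unadjusted one-way ANOVA.
#' @param contrasts if `TRUE`, append Tukey-Kramer contrasts via
#'   [tukey_hsd()].
#' @return A `scan_record` list: `n_used`, `F`, `df1`, `df2`, `p`,
#'   `adj_means`, `mse`, `group_n`, and optionally `contrasts`.
#' @export
fit_ancova <- function(y, st, covariates = default_covariates(),
                       contrasts = FALSE) {
  stopifnot(length(y) == nrow(st))
  group_all <- factor(st$endophenotype)
  keep <- !is.na(y)
  if (length(covariates)) {
    covars_all <- as.matrix(st[, covariates, drop = FALSE])
    keep <- keep & stats::complete.cases(covars_all)
  }
  group <- droplevels(factor(st$endophenotype[keep]))
  emptied <- setdiff(levels(group_all), levels(group))
  tab <- table(group)
  small <- names(tab)[tab < 2]
  if (length(emptied) || length(small))
    stop("endophenotype group(s) emptied or too small after missingness: ",
         paste(union(emptied, small), collapse = ", "))
  yk <- y[keep]
  if (stats::var(yk) == 0) {
    rec <- list(n_used = sum(keep), F = NA_real_, df1 = nlevels(group) - 1,
                df2 = NA_integer_, p = NA_real_, adj_means = NULL, mse = NA,
                group_n = as.integer(tab), reason = "monomorphic")
    class(rec) <- "scan_record"
    return(rec)
  }
  covars <- if (length(covariates))
    as.matrix(st[keep, covariates, drop = FALSE])
  else matrix(numeric(0), nrow = sum(keep), ncol = 0)
  rec <- ancova_engine(yk, group, covars)
  rec$reason <- NA_character_
  if (contrasts)
    rec$contrasts <- tukey_hsd(rec$adj_means, rec$mse, rec$group_n, rec$df2,
                               rec$vcov_unit)
  class(rec) <- "scan_record"
  rec
}

#' @export
print.scan_record <- function(x, ...) {
  if (!is.na(x$reason) && x$reason == "monomorphic") {
    cat("scan_record: monomorphic variant, no test\n")
    return(invisible(x))
  }
  cat(sprintf("scan_record: F(%d, %d) = %.3f, p = %.3g, n = %d\n",
              x$df1, x$df2, x$F, x$p, x$n_used))
  cat("adjusted group means:",
      paste(sprintf("%s=%.3f", names(x$adj_means), x$adj_means),
            collapse = " "), "\n")
  if (!is.null(x$contrasts)) {
    cat("Tukey contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Tukey-Kramer post-hoc contrasts
#'
#' All `K(K-1)/2` pairwise contrasts of the (covariate-adjusted) group
#' means. The familywise-adjusted p-value is the studentized-range upper
#' tail of `q = |diff| / se_ab` at `(K, df2)`. Without a model covariance
#' (`vcov_unit = NULL`) the Tukey-Kramer standard error for unequal group
#' sizes is used, `se_ab = sqrt(MSE * (1/n_a + 1/n_b) / 2)`. When the model
#' includes covariates that are not balanced across groups (an age gradient,
#' ancestry structure), that formula understates the sampling variance of
#' *adjusted* mean differences, so contrasts produced inside the ANCOVA use
#' the exact model-based variance of the group-effect contrast,
#' `se_ab = sqrt(MSE * c'(X'X)^-1 c / 2)`; the two coincide whenever there
#' are no covariates (or they are orthogonal to the factor).
#'
#' @param adj_means named vector of K adjusted group means.
#' @param mse residual mean square of the full model.
#' @param group_n group sizes (same order as `adj_means`).
#' @param df2 residual degrees of freedom.
#' @param vcov_unit optional K x K unit covariance of the group effects
#'   (reference group row/col zero), as returned inside [fit_ancova()].
#' @return data.frame `group_a group_b diff se q p_adj`.
#' @export
tukey_hsd <- function(adj_means, mse, group_n, df2, vcov_unit = NULL) {
  out <- tukey_raw(adj_means, mse, group_n, vcov_unit)
  if (!is.finite(mse) || mse <= 0) stop("MSE must be positive")
  if (any(group_n < 2)) stop("every group needs n >= 2")
  out$p_adj <- studentized_range_sf(out$q, length(adj_means), df2)
  out
}

#' Genome-wide ANCOVA scan
#'
#' Runs [fit_ancova()] for every variant in the cohort. Per-variant failures
#' (monomorphic variants, emptied groups, rank deficiency) are recorded as NA
#' rows with a reason and never abort the scan.
#'
#' @param gm A `genotype_matrix` (post-QC).
#' @param st matching sample table.
#' @param alpha_gw genome-wide significance threshold (default 5e-8).
#' @param covariates covariate columns of `st` to adjust for.
#' @param contrasts `"flagged"` (Tukey contrasts only for genome-wide
#'   significant variants, the default), `"all"`, or `"none"`.
#' @param progress_every log progress every this many variants (0 = silent).
#' @return List of class `endo_scan` with `records` (one row per variant:
#'   `variant chrom pos n F df1 df2 p gw_flag adj_mean_1..K reason`) and
#'   `contrasts` (`variant group_a group_b diff se q p_adj`).
#' @export
genome_scan <- function(gm, st, alpha_gw = 5e-8,
                        covariates = default_covariates(),
                        contrasts = c("flagged", "all", "none"),
                        progress_every = 10000) {
  contrasts <- match.arg(contrasts)
  st <- st[match(gm$samples, st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("samples in genotypes missing from table")
  group <- factor(st$endophenotype)
  K <- nlevels(group)
  covars <- if (length(covariates))
    as.matrix(st[, covariates, drop = FALSE])
  else matrix(numeric(0), nrow = nrow(st), ncol = 0)
  nv <- nrow(gm$dosage)
  recs <- vector("list", nv)
  all_complete <- !anyNA(covars)
  for (i in seq_len(nv)) {
    y <- gm$dosage[i, ]
    rec <- tryCatch({
      keep <- !is.na(y)
      if (!all_complete) keep <- keep & stats::complete.cases(covars)
      if (all(keep) && stats::var(y) > 0) {
        r <- ancova_engine(y, group, covars, check_rank = (i == 1))
        r$reason <- NA_character_
        r
      } else {
        fit_ancova(y, st, covariates)
      }
    }, error = function(e) {
      list(n_used = NA_integer_, F = NA_real_, df1 = K - 1, df2 = NA_integer_,
           p = NA_real_, adj_means = NULL, mse = NA_real_, group_n = NULL,
           reason = conditionMessage(e))
    })
    recs[[i]] <- rec
    if (progress_every > 0 && i %% progress_every == 0)
      message("scanned ", i, " / ", nv, " variants")
  }
  am <- t(vapply(recs, function(r)
    if (is.null(r$adj_means)) rep(NA_real_, K) else unname(r$adj_means),
    numeric(K)))
  colnames(am) <- paste0("adj_mean_", levels(group))
  records <- data.frame(
    variant = gm$variants$id, chrom = gm$variants$chrom, pos = gm$variants$pos,
    n = vapply(recs, function(r) as.integer(r$n_used %||% NA), integer(1)),
    F = vapply(recs, function(r) r$F, numeric(1)),
    df1 = vapply(recs, function(r) as.integer(r$df1), integer(1)),
    df2 = vapply(recs, function(r) as.integer(r$df2 %||% NA), integer(1)),
    p = vapply(recs, function(r) r$p, numeric(1)),
    stringsAsFactors = FALSE)
  records$gw_flag <- !is.na(records$p) & records$p <= alpha_gw
  records <- cbind(records, am)
  records$reason <- vapply(recs, function(r) r$reason %||% NA_character_,
                           character(1))
  want <- switch(contrasts,
                 all = which(!is.na(records$p)),
                 flagged = which(records$gw_flag),
                 none = integer(0))
  ctr <- if (length(want)) {
    # shared (K, df2) lets the studentized-range tail be evaluated in bulk
    pieces <- lapply(want, function(i) {
      r <- recs[[i]]
      tk <- tukey_raw(r$adj_means, r$mse, r$group_n, r$vcov_unit)
      tk$variant <- gm$variants$id[i]
      tk$df2 <- r$df2
      tk
    })
    ctab <- do.call(rbind, pieces)
    ctab$p_adj <- NA_real_
    for (d in unique(ctab$df2)) {
      sel <- ctab$df2 == d
      ctab$p_adj[sel] <- studentized_range_sf(ctab$q[sel], K, d)
    }
    ctab[, c("variant", "group_a", "group_b", "diff", "se", "q", "p_adj")]
  } else {
    data.frame(variant = character(), group_a = character(),
               group_b = character(), diff = numeric(), se = numeric(),
               q = numeric(), p_adj = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(records = records, contrasts = ctr, alpha_gw = alpha_gw,
                 K = K), class = "endo_scan")
}

# contrasts without the (expensive) tail probability; filled in batch
tukey_raw <- function(adj_means, mse, group_n, vcov_unit = NULL) {
  K <- length(adj_means)
  if (K < 2) stop("need at least two groups")
  labs <- names(adj_means)
  if (is.null(labs)) labs <- as.character(seq_len(K))
  pairs <- utils::combn(K, 2)
  a <- pairs[2, ]; b <- pairs[1, ]       # report higher category first (4-1)
  diff <- unname(adj_means[a] - adj_means[b])
  se <- if (is.null(vcov_unit)) {
    sqrt(mse * (1 / group_n[a] + 1 / group_n[b]) / 2)
  } else {
    v <- vcov_unit[cbind(a, a)] + vcov_unit[cbind(b, b)] -
      2 * vcov_unit[cbind(a, b)]
    sqrt(mse * v / 2)
  }
  data.frame(group_a = labs[a], group_b = labs[b], diff = diff, se = se,
             q = abs(diff) / se, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.endo_scan <- function(x, ...) {
  cat(sprintf("endo_scan: %d variants, %d genome-wide significant (p <= %g)\n",
              nrow(x$records), sum(x$records$gw_flag), x$alpha_gw))
  invisible(x)
}

#' Write scan outputs
#'
#' Writes the per-variant records TSV, the contrasts TSV, and a
#' Manhattan-ready `chrom pos p` table.
#'
#' @param scan an `endo_scan` object.
#' @param prefix output path prefix; files `<prefix>_scan.tsv`,
#'   `<prefix>_contrasts.tsv`, `<prefix>_manhattan.tsv` are created.
#' @export
write_scan <- function(scan, prefix) {
  utils::write.table(scan$records, paste0(prefix, "_scan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scan$contrasts, paste0(prefix, "_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$records[, c("chrom", "pos", "p")],
                     paste0(prefix, "_manhattan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Severity-trend regression
#'
#' Tests for a monotone dosage trend along a continuous severity score with
#' the linear model `dosage ~ score + covariates` (reverse regression,
#' matching the ANCOVA orientation). When no per-sample score is supplied the
#' ordinal group index 1..K is used.
#'
#' @param y dosage vector.
#' @param st sample table.
#' @param score per-sample severity score; defaults to the endophenotype
#'   index.
#' @param covariates covariate columns of `st`.
#' @return List `slope`, `se`, `p`, `n_used` (class `trend_record`).
#' @export
severity_trend <- function(y, st, score = NULL,
                           covariates = default_covariates()) {
  if (is.null(score)) score <- as.numeric(st$endophenotype)
  stopifnot(length(y) == nrow(st), length(score) == nrow(st))
  keep <- !is.na(y) & !is.na(score)
  if (length(unique(score[keep])) < 2)
    stop("severity score is constant; trend undefined")
  covars <- if (length(covariates))
    as.matrix(st[keep, covariates, drop = FALSE])
  else matrix(numeric(0), nrow = sum(keep), ncol = 0)
  X <- cbind(1, score = score[keep], covars)
  fit <- stats::lm.fit(X, y[keep])
  df <- sum(keep) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  slope <- unname(fit$coefficients[2])
  tval <- slope / se
  structure(list(slope = slope, se = se,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 n_used = sum(keep)),
            class = "trend_record")
}
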