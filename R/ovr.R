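# One-vs-rest logistic comparison arm and multiplicity accounting.

#' One-vs-rest logistic regression for one endophenotype
#'
#' Fits `I(endophenotype == k) ~ dosage + covariates` by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()], convergence
#' tolerance 1e-8, up to 100 iterations) and reports the Wald test for the
#' dosage coefficient. Non-convergence or (quasi-)separation is flagged:
#' `converged = FALSE` with NA estimates, never a silently unstable fit.
#'
#' @param y binary outcome vector (1 = in endophenotype k, 0 = rest).
#' @param x dosage vector.
#' @param st sample table supplying the covariates.
#' @param covariates covariate column names in `st`.
#' @return List of class `ovr_record`: `beta`, `se`, `OR`, `p`, `converged`,
#'   `n_case`, `n_control`, `deviance`.
#' @export
fit_ovr <- function(y, x, st, covariates = default_covariates()) {
  stopifnot(length(y) == length(x), length(y) == nrow(st))
  keep <- !is.na(x) & !is.na(y)
  y <- y[keep]; x <- x[keep]
  if (length(unique(y)) < 2)
    stop("one-vs-rest outcome has a single class; nothing to compare")
  covars <- if (length(covariates))
    as.matrix(st[keep, covariates, drop = FALSE])
  else matrix(numeric(0), nrow = sum(keep), ncol = 0)
  dat <- data.frame(.y = y, .x = x, covars)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co[".x", "Estimate"]
  se <- co[".x", "Std. Error"]
  # separation shows up as runaway coefficients / exploding Wald SEs
  separated <- !fit$converged || abs(beta) > 15 || se > 100 ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  rec <- if (separated) {
    list(beta = NA_real_, se = NA_real_, OR = NA_real_, p = NA_real_,
         converged = FALSE, n_case = sum(y == 1), n_control = sum(y == 0),
         deviance = NA_real_)
  } else {
    list(beta = beta, se = se, OR = exp(beta),
         p = 2 * stats::pnorm(abs(beta) / se, lower.tail = FALSE),
         converged = TRUE, n_case = sum(y == 1), n_control = sum(y == 0),
         deviance = fit$deviance)
  }
  structure(rec, class = "ovr_record")
}

#' @export
print.ovr_record <- function(x, ...) {
  if (!x$converged) {
    cat("ovr_record: did not converge (separation?)\n")
  } else {
    cat(sprintf("ovr_record: OR = %.3f (beta %.3f +/- %.3f), p = %.3g, %d/%d\n",
                x$OR, x$beta, x$se, x$p, x$n_case, x$n_control))
  }
  invisible(x)
}

#' One-vs-rest scan over variants and endophenotypes
#'
#' Runs [fit_ovr()] for every (variant, endophenotype) pair: K binary models
#' per variant, each category against all others.
#'
#' @param gm A `genotype_matrix`.
#' @param st matching sample table.
#' @param variants optional variant ids to restrict to (default: all).
#' @param covariates covariate columns of `st`.
#' @return data.frame `variant endophenotype n_case n_control beta se OR p
#'   converged`.
#' @export
ovr_scan <- function(gm, st, variants = NULL,
                     covariates = default_covariates()) {
  st <- st[match(gm$samples, st$sample_id), , drop = FALSE]
  if (!is.null(variants)) gm <- subset_genotypes(gm, variants = variants)
  cats <- sort(unique(st$endophenotype))
  out <- vector("list", nrow(gm$dosage) * length(cats))
  j <- 0
  for (i in seq_len(nrow(gm$dosage))) {
    x <- gm$dosage[i, ]
    for (k in cats) {
      j <- j + 1
      rec <- tryCatch(
        fit_ovr(as.integer(st$endophenotype == k), x, st, covariates),
        error = function(e) list(beta = NA, se = NA, OR = NA, p = NA,
                                 converged = FALSE, n_case = NA,
                                 n_control = NA))
      out[[j]] <- data.frame(variant = gm$variants$id[i], endophenotype = k,
                             n_case = rec$n_case, n_control = rec$n_control,
                             beta = rec$beta, se = rec$se, OR = rec$OR,
                             p = rec$p, converged = rec$converged,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Multiplicity accounting for a family of contrasts
#'
#' Counts nominally significant tests (`p < alpha`) and tests surviving a
#' Bonferroni correction at the exact per-test threshold `alpha / m`.
#'
#' @param p vector of p-values (one per contrast), or a data.frame with a
#'   `p` column.
#' @param alpha familywise error rate (default 0.05).
#' @return List of class `multiplicity_report`: `m`, `alpha`, `alpha_adj`,
#'   `n_nominal`, `n_bonferroni`.
#' @export
multiplicity <- function(p, alpha = 0.05) {
  if (is.data.frame(p)) p <- p$p
  p <- as.numeric(p)
  if (!length(p)) stop("need at least one p-value")
  m <- length(p)
  alpha_adj <- alpha / m
  structure(list(m = m, alpha = alpha, alpha_adj = alpha_adj,
                 n_nominal = sum(p < alpha, na.rm = TRUE),
                 n_bonferroni = sum(p <= alpha_adj, na.rm = TRUE)),
            class = "multiplicity_report")
}

#' @export
print.multiplicity_report <- function(x, ...) {
  cat(sprintf(
    "multiplicity_report: m = %d, alpha = %g (per-test %.4g)\n", x$m,
    x$alpha, x$alpha_adj))
  cat(sprintf("  nominal p < %g:     %d (%.0f%%)\n", x$alpha, x$n_nominal,
              100 * x$n_nominal / x$m))
  cat(sprintf("  Bonferroni p <= %.4g: %d (%.0f%%)\n", x$alpha_adj,
              x$n_bonferroni, 100 * x$n_bonferroni / x$m))
  invisible(x)
}
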