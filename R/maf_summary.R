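# Per-endophenotype allele-frequency tables, delta-MAF, and cross-cohort
# direction concordance.

#' Per-group minor-allele frequencies for one variant
#'
#' Group allele frequencies with the minor-allele fold chosen once on the
#' pooled sample, so per-group values are comparable (a group may exceed 0.5
#' after the pooled fold). Deltas are reported for the supplied contrasts
#' (pairs of group labels), plus the overall maximum pairwise delta.
#'
#' @param gm A `genotype_matrix`.
#' @param st matching sample table.
#' @param variant variant id.
#' @param contrasts optional data.frame with columns `group_a`, `group_b`
#'   (e.g. significant Tukey contrasts); deltas `maf[a] - maf[b]` are
#'   reported per row.
#' @return List of class `group_maf`: `variant`, `maf` (K per-group
#'   frequencies, NA for an all-missing group), `pooled`, `flipped`,
#'   `delta_max`, `deltas`.
#' @export
group_maf <- function(gm, st, variant, contrasts = NULL) {
  i <- match(variant, gm$variants$id)
  if (is.na(i)) stop("variant not found: ", variant)
  st <- st[match(gm$samples, st$sample_id), , drop = FALSE]
  d <- gm$dosage[i, ]
  f_pooled <- mean(d, na.rm = TRUE) / 2
  flipped <- !is.na(f_pooled) && f_pooled > 0.5
  if (flipped) d <- 2 - d
  groups <- sort(unique(st$endophenotype))
  maf <- vapply(groups, function(g) {
    dg <- d[st$endophenotype == g]
    if (all(is.na(dg))) NA_real_ else mean(dg, na.rm = TRUE) / 2
  }, numeric(1))
  names(maf) <- groups
  deltas <- if (!is.null(contrasts) && nrow(contrasts)) {
    data.frame(group_a = contrasts$group_a, group_b = contrasts$group_b,
               delta = maf[as.character(contrasts$group_a)] -
                 maf[as.character(contrasts$group_b)],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(group_a = character(), group_b = character(),
               delta = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(variant = variant, maf = maf,
                 pooled = min(f_pooled, 1 - f_pooled), flipped = flipped,
                 delta_max = if (all(is.na(maf))) NA_real_
                             else max(maf, na.rm = TRUE) -
                                  min(maf, na.rm = TRUE),
                 deltas = deltas),
            class = "group_maf")
}

#' @export
print.group_maf <- function(x, ...) {
  cat(sprintf("group_maf %s: pooled %.3f%s, delta_max %.3f\n", x$variant,
              x$pooled, if (x$flipped) " (folded)" else "", x$delta_max))
  print(round(x$maf, 4))
  invisible(x)
}

#' Group-MAF table for a set of variants
#'
#' @param gm A `genotype_matrix`.
#' @param st matching sample table.
#' @param variants variant ids (default: all).
#' @return data.frame `variant maf_1..K delta_max`.
#' @export
maf_table <- function(gm, st, variants = NULL) {
  if (is.null(variants)) variants <- gm$variants$id
  rows <- lapply(variants, function(v) {
    g <- group_maf(gm, st, v)
    out <- data.frame(variant = v, t(g$maf), delta_max = g$delta_max,
                      stringsAsFactors = FALSE)
    names(out) <- c("variant", paste0("maf_", names(g$maf)), "delta_max")
    out
  })
  do.call(rbind, rows)
}

#' Cross-cohort direction concordance
#'
#' A variant's direction in a cohort is the sign of the mean MAF in the two
#' most severe groups minus the mean MAF in the two mildest groups. A
#' variant is concordant when that sign agrees across the two cohorts.
#'
#' @param summary_a,summary_b [maf_table()] outputs for the two cohorts
#'   (same variants).
#' @return data.frame `variant dir_a dir_b concordant`, with attributes
#'   `n_concordant` and `n_total`.
#' @export
direction_concordance <- function(summary_a, summary_b) {
  if (!setequal(summary_a$variant, summary_b$variant))
    stop("the two summaries must cover the same variants")
  summary_b <- summary_b[match(summary_a$variant, summary_b$variant), ,
                         drop = FALSE]
  sev_dir <- function(s) {
    mafs <- as.matrix(s[, grep("^maf_", names(s)), drop = FALSE])
    K <- ncol(mafs)
    if (K < 4) stop("need >= 4 groups for the severe-vs-mild aggregate")
    sign(rowMeans(mafs[, c(K - 1, K), drop = FALSE]) -
           rowMeans(mafs[, 1:2, drop = FALSE]))
  }
  da <- sev_dir(summary_a)
  db <- sev_dir(summary_b)
  out <- data.frame(variant = summary_a$variant, dir_a = da, dir_b = db,
                    concordant = da == db, stringsAsFactors = FALSE)
  attr(out, "n_concordant") <- sum(out$concordant, na.rm = TRUE)
  attr(out, "n_total") <- nrow(out)
  out
}

#' Pooled MAF from group frequencies (conservation check helper)
#'
#' The pooled allele frequency equals the group-size-weighted mean of group
#' frequencies; exposed for testing and reporting.
#'
#' @param maf per-group frequencies.
#' @param n per-group sample counts (complete dosages).
#' @export
pooled_from_groups <- function(maf, n) sum(maf * n) / sum(n)
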