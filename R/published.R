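# Published association results for the six replicated endophenotype-GWAS
# loci (CAMP discovery / GACRS replication), shipped as plain-text tables.
# These printed summary statistics are inputs for significance accounting;
# the underlying individual-level cohort data are not publicly packaged.

#' Published one-vs-rest logistic results for the six replicated loci
#'
#' Odds ratios and p-values for each endophenotype-vs-rest contrast of the
#' six replicated loci, in both the discovery (CAMP) and replication
#' (GACRS) childhood-asthma cohorts: 6 variants x 5 endophenotypes x 2
#' cohorts.
#'
#' @param cohort optional cohort filter (`"CAMP"` or `"GACRS"`).
#' @return data.frame `snp endophenotype cohort or p`.
#' @export
published_ovr_results <- function(cohort = NULL) {
  x <- utils::read.delim(system.file("extdata", "published_ovr.tsv",
                                     package = "endoscan"),
                         stringsAsFactors = FALSE)
  if (!is.null(cohort)) x <- x[x$cohort == cohort, , drop = FALSE]
  x
}

#' Published ANCOVA results for the six replicated loci
#'
#' Per-cohort F statistics, p-values, and the Tukey-corrected post-hoc
#' contrasts that remained significant, for the six LD-independent
#' genome-wide significant loci.
#'
#' @param cohort optional cohort filter.
#' @return data.frame `snp region cohort F p posthoc` (posthoc a
#'   comma-separated list of `a-b` group contrasts).
#' @export
published_ancova_results <- function(cohort = NULL) {
  x <- utils::read.delim(system.file("extdata", "published_ancova.tsv",
                                     package = "endoscan"),
                         stringsAsFactors = FALSE)
  if (!is.null(cohort)) x <- x[x$cohort == cohort, , drop = FALSE]
  x
}

#' Published post-hoc contrasts as a contrast table
#'
#' Expands the `posthoc` column of [published_ancova_results()] into one
#' row per significant contrast, in the shape [contrast_count()] expects.
#'
#' @param cohort cohort to expand (`"CAMP"` or `"GACRS"`).
#' @return data.frame `variant group_a group_b significant`.
#' @export
published_contrasts <- function(cohort) {
  x <- published_ancova_results(cohort)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    cs <- strsplit(x$posthoc[i], ",", fixed = TRUE)[[1]]
    ab <- do.call(rbind, strsplit(trimws(cs), "-", fixed = TRUE))
    data.frame(variant = x$snp[i], group_a = ab[, 1], group_b = ab[, 2],
               significant = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
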