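# Cohort input/output: genotype matrices, sample tables, QC filters.

#' Construct a genotype matrix
#'
#' Container for a variants-by-samples dosage matrix plus variant metadata.
#' Dosages are expected alternate-allele counts in \[0, 2\]; `NA` marks a
#' missing call.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param samples character vector of sample identifiers.
#' @param dosage numeric matrix, one row per variant, one column per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage) {
  variants <- as.data.frame(variants)
  needed <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(variants)))
    stop("variants must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique")
  if (any(variants$pos < 1))
    stop("positions are 1-based and must be >= 1")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants) || ncol(dosage) != length(samples))
    stop("dosage must be length(variants) x length(samples)")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  dimnames(dosage) <- list(variants$id, samples)
  structure(list(variants = variants, samples = as.character(samples),
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  missing dosage: %.2f%%\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variant and/or sample
#'
#' @param gm A `genotype_matrix`.
#' @param variants indices, logical mask, or ids selecting variants.
#' @param samples indices, logical mask, or ids selecting samples.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(nrow(gm$dosage)) else {
    if (is.character(variants)) match(variants, gm$variants$id) else variants
  }
  si <- if (is.null(samples)) seq_len(ncol(gm$dosage)) else {
    if (is.character(samples)) match(samples, gm$samples) else samples
  }
  if (anyNA(vi)) stop("unknown variant id(s)")
  if (anyNA(si)) stop("unknown sample id(s)")
  genotype_matrix(gm$variants[vi, , drop = FALSE], gm$samples[si],
                  gm$dosage[vi, si, drop = FALSE])
}

#' Read genotype dosages from a VCF file
#'
#' Parses a (optionally bgzipped) VCF and builds a [genotype_matrix()] from
#' either the `DS` FORMAT field (imputed dosages, copied through) or the `GT`
#' field (diploid hard calls converted to alternate-allele counts: `0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> missing). Multi-allelic records are
#' skipped with a warning; only biallelic SNVs/indels are retained.
#'
#' @param path VCF file path.
#' @param dosage_source `"DS"` or `"GT"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, dosage_source = c("DS", "GT")) {
  dosage_source <- match.arg(dosage_source)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped: ",
            paste(utils::head(fix$ID[multi], 5), collapse = ", "),
            if (sum(multi) > 5) ", ..." else "")
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path)
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!dosage_source %in% fmt_fields)
    stop("FORMAT field '", dosage_source, "' absent from ", path,
         " (first variant: ", fix$ID[1], ")")
  if (dosage_source == "DS") {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- ds[keep, , drop = FALSE]
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
    dos <- gt_to_dosage(gt, fix$ID[keep])
  }
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ":", fix$ALT)[keep][
      is.na(ids) | ids == "."]
  genotype_matrix(
    data.frame(id = ids, chrom = fix$CHROM[keep],
               pos = as.integer(fix$POS[keep]),
               ref = fix$REF[keep], alt = fix$ALT[keep],
               stringsAsFactors = FALSE),
    colnames(vcf@gt)[-1], dos)
}

# GT strings -> alt-allele counts; errors on non-diploid calls.
gt_to_dosage <- function(gt, ids) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  canon <- gsub("|", "/", u, fixed = TRUE)
  bad <- !canon %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad)) {
    off <- which(matrix(gt %in% u[bad], nrow = nrow(gt)), arr.ind = TRUE)
    stop("non-diploid or unsupported GT '", u[bad][1], "' at variant ",
         ids[off[1, 1]])
  }
  map <- stats::setNames(c(0, 1, 1, 2, NA_real_),
                         c("0/0", "0/1", "1/0", "1/1", "./."))
  out <- matrix(map[gsub("|", "/", gt, fixed = TRUE)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix to a VCF file
#'
#' Minimal VCFv4.2 writer used for fixtures and round-tripping. Dosages are
#' written as the `DS` field (3 decimals) and, when all non-missing dosages
#' are integral, additionally as `GT` hard calls.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  d <- gm$dosage
  integral <- all(is.na(d) | d == round(d))
  fmt <- if (integral) "GT:DS" else "DS"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=endoscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alt allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  gt_str <- function(x) c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(x)]
  for (i in seq_len(nrow(d))) {
    v <- gm$variants[i, ]
    ds <- ifelse(is.na(d[i, ]), ".", formatC(d[i, ], digits = 3, format = "f"))
    cells <- if (integral) {
      g <- ifelse(is.na(d[i, ]), "./.", gt_str(round(d[i, ])))
      paste(g, ds, sep = ":")
    } else ds
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                       fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample table
#'
#' Tab-separated file with header
#' `sample_id endophenotype age sex pc1..pc<n>`. Endophenotype labels are
#' ordinal categories `1..K`; `sex` is a binary 0/1 code; `pc*` columns are
#' ancestry principal components.
#'
#' @param path TSV path.
#' @param n_pcs expected number of PC columns (default 10).
#' @return A validated data.frame.
#' @export
read_sample_table <- function(path, n_pcs = 10) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(st, n_pcs = n_pcs)
}

#' @rdname read_sample_table
#' @param st data.frame to validate in place of a file.
#' @export
validate_sample_table <- function(st, n_pcs = 10) {
  pcs <- paste0("pc", seq_len(n_pcs))
  needed <- c("sample_id", "endophenotype", "age", "sex", pcs)
  miss <- setdiff(needed, names(st))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(st$sample_id)) stop("duplicate sample_id values")
  if (!all(st$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  tab <- table(st$endophenotype)
  if (any(tab < 2))
    stop("every endophenotype category needs >= 2 samples; too few in: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  st$sample_id <- as.character(st$sample_id)
  st$endophenotype <- as.integer(st$endophenotype)
  st
}

#' Write a sample table TSV
#' @param st sample table data.frame.
#' @param path output path.
#' @export
write_sample_table <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Folded minor-allele frequency of a dosage vector
#'
#' `min(f, 1 - f)` where `f = mean(dosage) / 2` over non-missing entries.
#'
#' @param dosages numeric vector of dosages in \[0, 2\].
#' @return MAF in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("MAF undefined: all dosages missing")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on hard-call genotype counts: conditional on the
#' allele counts, the p-value sums the probabilities of every heterozygote
#' configuration whose probability does not exceed that of the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * n_AA + n_Aa                  # allele-A count
  # feasible heterozygote counts share the parity of nA
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nA + hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp)
  p_obs <- p[match(n_Aa, hets)]
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Round dosages to hard calls for HWE; calls further than `tol` from an
# integer are excluded from the counts (soft imputed dosages carry no
# reliable genotype).
hard_call_counts <- function(dosages, tol = 0.1) {
  d <- dosages[!is.na(dosages)]
  r <- round(d)
  ok <- abs(d - r) <= tol
  c(n_AA = sum(r[ok] == 0), n_Aa = sum(r[ok] == 1), n_aa = sum(r[ok] == 2))
}

#' QC thresholds
#'
#' @param variant_call_rate_min minimum per-variant call rate (default 0.95).
#' @param maf_min minimum folded minor-allele frequency (default 0.05).
#' @param hwe_p_min minimum Hardy-Weinberg exact p (default 1e-6).
#' @param sample_missing_max maximum per-sample missingness (default 0.05).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.95, maf_min = 0.05,
                          hwe_p_min = 1e-6, sample_missing_max = 0.05) {
  thr <- list(variant_call_rate_min = variant_call_rate_min,
              maf_min = maf_min, hwe_p_min = hwe_p_min,
              sample_missing_max = sample_missing_max)
  if (any(unlist(thr) <= 0 | unlist(thr) >= 1))
    stop("all QC thresholds must lie in (0, 1)")
  structure(thr, class = "qc_thresholds")
}

#' Apply cohort quality control
#'
#' Filter order is fixed: (1) drop samples whose genotype missingness exceeds
#' `sample_missing_max`; (2) on the remaining samples, drop variants failing
#' the call-rate, MAF, or Hardy-Weinberg gates. Samples absent from either
#' input are dropped first with reason `"unmatched"`. Every removal is listed
#' in the returned report.
#'
#' @param gm A `genotype_matrix`.
#' @param st A sample table (see [read_sample_table()]).
#' @param thr A [qc_thresholds()] object.
#' @return List with elements `genotypes`, `samples`, and `report`
#'   (data.frame `item type reason value threshold`).
#' @export
apply_qc <- function(gm, st, thr = qc_thresholds()) {
  report <- data.frame(item = character(), type = character(),
                       reason = character(), value = numeric(),
                       threshold = numeric(), stringsAsFactors = FALSE)
  add <- function(item, type, reason, value, threshold) {
    rbind(report, data.frame(item = item, type = type, reason = reason,
                             value = value, threshold = threshold))
  }
  common <- intersect(gm$samples, st$sample_id)
  if (!length(common)) stop("no samples shared between genotypes and table")
  for (s in setdiff(gm$samples, common))
    report <- add(s, "sample", "unmatched", NA, NA)
  for (s in setdiff(st$sample_id, common))
    report <- add(s, "sample", "unmatched", NA, NA)
  gm <- subset_genotypes(gm, samples = common)
  st <- st[match(common, st$sample_id), , drop = FALSE]

  # (1) sample missingness
  smiss <- colMeans(is.na(gm$dosage))
  bad_s <- smiss > thr$sample_missing_max
  for (i in which(bad_s))
    report <- add(gm$samples[i], "sample", "missingness", smiss[i],
                  thr$sample_missing_max)
  if (any(bad_s)) {
    gm <- subset_genotypes(gm, samples = which(!bad_s))
    st <- st[!bad_s, , drop = FALSE]
  }

  # (2) variant gates on the surviving samples
  call_rate <- rowMeans(!is.na(gm$dosage))
  maf <- apply(gm$dosage, 1, function(d)
    if (all(is.na(d))) NA_real_ else minor_allele_frequency(d))
  hwe_p <- apply(gm$dosage, 1, function(d) {
    cc <- hard_call_counts(d)
    if (sum(cc) < 1) NA_real_
    else hwe_exact_test(cc["n_AA"], cc["n_Aa"], cc["n_aa"])
  })
  drop_v <- rep(FALSE, nrow(gm$dosage))
  for (i in seq_along(drop_v)) {
    id <- gm$variants$id[i]
    if (is.na(maf[i]) || call_rate[i] < thr$variant_call_rate_min) {
      report <- add(id, "variant", "call_rate", call_rate[i],
                    thr$variant_call_rate_min)
      drop_v[i] <- TRUE
    } else if (maf[i] < thr$maf_min) {
      report <- add(id, "variant", "maf", maf[i], thr$maf_min)
      drop_v[i] <- TRUE
    } else if (!is.na(hwe_p[i]) && hwe_p[i] < thr$hwe_p_min) {
      report <- add(id, "variant", "hwe", hwe_p[i], thr$hwe_p_min)
      drop_v[i] <- TRUE
    }
  }
  if (all(drop_v) || nrow(st) == 0) stop("no data survive QC")
  gm <- subset_genotypes(gm, variants = which(!drop_v))
  list(genotypes = gm, samples = st, report = report)
}

#' Write a QC report TSV
#' @param report the `report` element returned by [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
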