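# Minimal base-graphics views of the three standard outputs.

#' Manhattan plot of a scan
#'
#' @param scan an `endo_scan` object or its `records` data.frame.
#' @param alpha_gw genome-wide line (default 5e-8).
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(scan, alpha_gw = 5e-8, ...) {
  rec <- if (inherits(scan, "endo_scan")) scan$records else scan
  rec <- rec[!is.na(rec$p), , drop = FALSE]
  chrom <- factor(rec$chrom, unique(rec$chrom))
  x <- order(chrom, rec$pos)
  rec <- rec[x, , drop = FALSE]
  graphics::plot(seq_len(nrow(rec)), -log10(rec$p),
                 col = c("grey30", "steelblue")[1 + as.integer(chrom[x]) %% 2],
                 pch = 20, xlab = "variant (genome order)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(alpha_gw), lty = 2, col = "red")
  invisible(rec)
}

#' Bar plot of per-group minor-allele frequencies
#'
#' @param gmaf a [group_maf()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_group_maf <- function(gmaf, ...) {
  graphics::barplot(gmaf$maf, xlab = "endophenotype", ylab = "MAF",
                    main = gmaf$variant, ...)
  invisible(gmaf)
}

#' One-vs-rest ROC curves
#'
#' @param report an `auc_report` from [fit_ovr_enet()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(report, ...) {
  pts <- roc_points(report)
  classes <- unique(pts$class)
  graphics::plot(NULL, xlim = 0:1, ylim = 0:1, xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  for (i in seq_along(classes)) {
    p <- pts[pts$class == classes[i], ]
    graphics::lines(p$fpr, p$tpr, col = i + 1)
  }
  graphics::legend("bottomright",
                   sprintf("%s (AUC %.2f)", classes, report$per_class),
                   col = seq_along(classes) + 1, lty = 1, cex = 0.8)
  invisible(pts)
}
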