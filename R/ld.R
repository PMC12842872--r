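# Dosage-based linkage disequilibrium and greedy clumping.

#' Squared dosage correlation between two variants
#'
#' Squared Pearson correlation over pairwise-complete samples, the standard
#' dosage-based r-squared used for LD pruning.
#'
#' @param d1,d2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
dosage_r2 <- function(d1, d2) {
  stopifnot(length(d1) == length(d2))
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 3) stop("need >= 3 pairwise-complete samples")
  if (sum(ok) < 0.8 * length(d1))
    message("dosage_r2: only ", sum(ok), "/", length(d1),
            " pairwise-complete samples")
  x <- d1[ok]; y <- d2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("r-squared undefined for a constant dosage vector")
  stats::cor(x, y)^2
}

#' Clumping parameters
#'
#' Variant-count sliding windows: width `window` SNPs advancing by `step`
#' SNPs; within a shared window, variants correlated with an index variant
#' at `r2 >= r2_max` are clumped into it.
#'
#' @param window window width in variants (default 250).
#' @param step step size in variants (default 50).
#' @param r2_max r-squared threshold (default 0.5).
#' @export
clump_params <- function(window = 250, step = 50, r2_max = 0.5) {
  if (step <= 0 || window <= 0 || step > window)
    stop("need 0 < step <= window")
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must be in (0, 1)")
  structure(list(window = window, step = step, r2_max = r2_max),
            class = "clump_params")
}

# Do chromosome-local variant ranks i and j (i <= j) co-occur in at least
# one sliding window of `window` variants with starts 1, 1+step, ...?
shares_window <- function(i, j, window, step) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  s_best <- ((lo - 1) %/% step) * step + 1   # last window start at or before lo
  hi <= s_best + window - 1
}

#' Greedy LD clumping of scan hits
#'
#' Reduces a set of associated variants to LD-independent index variants:
#' repeatedly take the remaining variant with the smallest p as an index,
#' then remove every remaining variant on the same chromosome that shares a
#' sliding window with it and has dosage `r2 >= r2_max` with it. Ties on p
#' are broken deterministically by `(chrom, pos, id)`. Variants whose
#' r-squared cannot be computed (constant dosages, too few complete pairs)
#' are retained conservatively with a warning.
#'
#' @param results data.frame with columns `variant` and `p` (e.g. the
#'   `records` of [genome_scan()], typically pre-filtered to significant
#'   hits).
#' @param gm `genotype_matrix` holding the dosages of (at least) those
#'   variants, position-sorted within chromosome.
#' @param params a [clump_params()] object.
#' @return data.frame `index_variant p n_clumped members`, one row per
#'   index variant, in selection order.
#' @export
clump <- function(results, gm, params = clump_params()) {
  empty <- data.frame(index_variant = character(), p = numeric(),
                      n_clumped = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (nrow(results) == 0) return(empty)
  idx <- match(results$variant, gm$variants$id)
  if (anyNA(idx)) stop("variant(s) absent from genotype matrix: ",
                       paste(utils::head(results$variant[is.na(idx)], 3),
                             collapse = ", "))
  v <- gm$variants[idx, , drop = FALSE]
  # chromosome-local variant ranks in the full matrix define the windows
  full_rank <- stats::ave(seq_len(nrow(gm$variants)), gm$variants$chrom,
                          FUN = seq_along)
  if (is.unsorted_within(gm$variants$chrom, gm$variants$pos))
    stop("genotype matrix must be position-sorted within chromosome")
  rank_in_chrom <- full_rank[idx]
  ord <- order(results$p, v$chrom, v$pos, v$id)
  remaining <- ord
  out <- list()
  while (length(remaining)) {
    lead <- remaining[1]
    remaining <- remaining[-1]
    same_chrom <- v$chrom[remaining] == v$chrom[lead]
    in_win <- same_chrom &
      shares_window(rank_in_chrom[remaining], rank_in_chrom[lead],
                    params$window, params$step)
    clumped <- logical(length(remaining))
    for (jj in which(in_win)) {
      r2 <- tryCatch(dosage_r2(gm$dosage[idx[lead], ],
                               gm$dosage[idx[remaining[jj]], ]),
                     error = function(e) NA_real_)
      if (is.na(r2)) {
        warning("r2 undefined for ", results$variant[remaining[jj]],
                " vs index ", results$variant[lead], "; retained")
      } else if (r2 >= params$r2_max) clumped[jj] <- TRUE
    }
    out[[length(out) + 1]] <- data.frame(
      index_variant = results$variant[lead], p = results$p[lead],
      n_clumped = sum(clumped),
      members = paste(results$variant[remaining[clumped]], collapse = ","),
      stringsAsFactors = FALSE)
    remaining <- remaining[!clumped]
  }
  do.call(rbind, out)
}

is.unsorted_within <- function(chrom, pos) {
  any(vapply(split(pos, chrom), is.unsorted, logical(1)))
}
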