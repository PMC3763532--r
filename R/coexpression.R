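#' Pearson correlation of two read-count vectors
#'
#' Standard Pearson correlation on raw (absolute) read counts across
#' tissues/stages; no transformation is applied by default. A vector with
#' zero variance makes the correlation undefined: the result is `NA_real_`
#' and such pairs are excluded from summaries rather than imputed as 0.
#'
#' @param x,y Equal-length numeric vectors of non-negative counts,
#'   length >= 3.
#' @param log1p Apply `log1p` to both vectors first (off by default).
#' @return Correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_counts <- function(x, y, log1p = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (log1p) {
    x <- base::log1p(x)
    y <- base::log1p(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Co-expression of neighbouring microRNAs as a function of genomic distance
#'
#' Enumerates neighbouring precursor pairs (by default: consecutive loci
#' along a chromosome on the same strand; optionally all same-chromosome
#' same-strand pairs), computes each pair's genomic gap and Pearson
#' correlation of read counts, assigns the pair to a distance bin, and
#' summarises the correlations per bin (box-plot statistics).
#'
#' @param loci A `mirna_loci` table for one species.
#' @param expr Expression matrix (rows = mirna_id, columns = samples).
#'   Loci missing from the matrix are skipped (count reported).
#' @param bins Strictly increasing distance bin edges in nt, first >= 0;
#'   the last bin is open-ended. Default `c(0, 1000, 10000, 100000)`.
#' @param all_pairs Use all same-chromosome same-strand pairs instead of
#'   consecutive neighbours.
#' @param log1p Passed to [pearson_counts()].
#' @return A list with `pairs` (data.frame: ids, gap, bin, r), `summary`
#'   (per bin: n, n_undefined, median, q1, q3; empty bins are flagged) and
#'   `n_skipped` (loci without expression rows).
#' @export
correlation_vs_distance <- function(loci, expr,
                                    bins = c(0, 1000, 10000, 100000),
                                    all_pairs = FALSE, log1p = FALSE) {
  loci <- validate_mirna_loci(loci)
  if (is.unsorted(bins, strictly = TRUE) || bins[1] < 0)
    stop("bins must be strictly increasing with first edge >= 0")
  expr <- validate_expression_matrix(expr)
  have <- loci$mirna_id %in% rownames(expr)
  n_skipped <- sum(!have)
  loci <- loci[have, , drop = FALSE]
  pairs <- list()
  k <- 0L
  for (key in unique(paste(loci$chrom, loci$strand))) {
    sub <- loci[paste(loci$chrom, loci$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- if (all_pairs) utils::combn(nrow(sub), 2, simplify = FALSE) else
      lapply(seq_len(nrow(sub) - 1), function(i) c(i, i + 1L))
    for (p in idx) {
      k <- k + 1L
      gap <- pairwise_gap(sub[p[1], ], sub[p[2], ])
      pairs[[k]] <- data.frame(
        mirna_a = sub$mirna_id[p[1]], mirna_b = sub$mirna_id[p[2]],
        gap = gap,
        r = pearson_counts(expr[sub$mirna_id[p[1]], ],
                           expr[sub$mirna_id[p[2]], ], log1p = log1p),
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (k > 0) do.call(rbind, pairs) else
    data.frame(mirna_a = character(), mirna_b = character(),
               gap = numeric(), r = numeric(), stringsAsFactors = FALSE)
  pairs$bin <- findInterval(pairs$gap, bins)
  labels <- bin_labels(bins)
  pairs$bin_label <- labels[pairs$bin]
  summary <- do.call(rbind, lapply(seq_along(labels), function(b) {
    r <- pairs$r[pairs$bin == b]
    rv <- r[!is.na(r)]
    data.frame(bin = b, bin_label = labels[b], n = length(rv),
               n_undefined = sum(is.na(r)),
               median = if (length(rv)) stats::median(rv) else NA_real_,
               q1 = if (length(rv)) unname(stats::quantile(rv, 0.25)) else NA_real_,
               q3 = if (length(rv)) unname(stats::quantile(rv, 0.75)) else NA_real_,
               empty = length(rv) == 0, stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summary, n_skipped = n_skipped)
}

bin_labels <- function(bins) {
  c(vapply(seq_len(length(bins) - 1), function(i)
    sprintf("[%g,%g)", bins[i], bins[i + 1]), ""),
    sprintf(">=%g", bins[length(bins)]))
}
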