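# Condition-vs-control enrichment. The window test is a deliberately
# simple stand-in for a dedicated differential peak caller: per window,
# a one-sided exact binomial test of the stimulated count against the
# depth-expected proportion, with Benjamini-Hochberg correction across
# windows. Externally produced differential peaks (BED) can be supplied
# instead and bypass it entirely.

#' Exact binomial enrichment test on per-window counts
#'
#' Tests whether `count_stim` out of `count_stim + count_ctrl` exceeds
#' the proportion expected from the library depths,
#' `depth_stim / (depth_stim + depth_ctrl)` (one-sided). Windows with
#' zero total count are untestable and get p = 1.
#'
#' @param windows Interval data.frame (`chrom`, `start`, `end`), one row
#'   per window.
#' @param count_stim,count_ctrl Integer tag counts per window.
#' @param depth_stim,depth_ctrl Total mapped tags per library.
#' @param fdr BH false-discovery-rate threshold for the `enriched` flag
#'   (default 0.1).
#' @return `windows` with `count_stim`, `count_ctrl`, `p_value`,
#'   `q_value` (BH across all supplied windows) and `enriched`
#'   (`q_value < fdr`) appended.
#' @export
differential_from_counts <- function(windows, count_stim, count_ctrl,
                                     depth_stim, depth_ctrl, fdr = 0.1) {
  if (depth_stim < 1 || depth_ctrl < 1) stop("library depths must be >= 1")
  n_tot <- count_stim + count_ctrl
  p0 <- depth_stim / (depth_stim + depth_ctrl)
  # one-sided upper tail: P(X >= count_stim), X ~ Binom(n_tot, p0)
  p <- ifelse(n_tot == 0, 1,
              stats::pbinom(count_stim - 1, n_tot, p0,
                            lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  windows$count_stim <- count_stim
  windows$count_ctrl <- count_ctrl
  windows$p_value <- p
  windows$q_value <- q
  windows$enriched <- q < fdr
  windows
}

#' Window-based differential enrichment from tag files
#'
#' Counts tags per window (by midpoint) in the stimulated and control
#' libraries and applies [differential_from_counts()].
#'
#' @param windows Interval data.frame.
#' @param tags_stim,tags_ctrl Tag tables.
#' @param stats_stim,stats_ctrl [library_stats()] per library.
#' @param fdr BH threshold (default 0.1).
#' @return See [differential_from_counts()].
#' @export
window_differential_test <- function(windows, tags_stim, tags_ctrl,
                                     stats_stim, stats_ctrl, fdr = 0.1) {
  cnt <- function(tags) {
    vapply(seq_len(nrow(windows)), function(i) {
      count_tags_in_window(tags, windows$chrom[i], windows$start[i],
                           windows$end[i], method = "midpoint")
    }, integer(1))
  }
  differential_from_counts(windows, cnt(tags_stim), cnt(tags_ctrl),
                           stats_stim$total_mapped,
                           stats_ctrl$total_mapped, fdr = fdr)
}

#' Flag enhancers as stimulus-inducible
#'
#' An enhancer is inducible when it intersects at least one enriched
#' H4ac window or at least one enriched H3K9ac window (stimulated vs
#' the matched unstimulated control, FDR < 0.1 upstream).
#'
#' @param calls Qualified enhancer call table.
#' @param h4ac_results,h3k9ac_results Results from
#'   [window_differential_test()] (either may be `NULL`).
#' @return `calls` with a logical `inducible` column.
#' @export
call_inducible_enhancers <- function(calls, h4ac_results = NULL,
                                     h3k9ac_results = NULL) {
  enriched_of <- function(res) {
    if (is.null(res)) return(res)
    res[res$enriched, , drop = FALSE]
  }
  hit <- rep(FALSE, nrow(calls))
  for (res in list(enriched_of(h4ac_results),
                   enriched_of(h3k9ac_results))) {
    if (!is.null(res) && nrow(res)) hit <- hit | overlaps_any(calls, res)
  }
  calls$inducible <- hit & calls$qualified
  calls
}

#' Quantile-normalize an expression matrix across samples
#'
#' After normalization every sample's sorted value vector is identical
#' (the column-mean reference distribution).
#'
#' @param mat Numeric matrix, genes x samples.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  out <- limma::normalizeQuantiles(as.matrix(mat))
  dimnames(out) <- dimnames(mat)
  out
}

#' Call stimulus-inducible genes from an expression matrix
#'
#' The matrix (log2-scale intensities) is quantile-normalized across
#' samples; per gene the log2 fold change of group means and a
#' two-sided unpaired t-test p-value are computed, and a gene is called
#' inducible when `log2_fold_change > lfc_threshold` and
#' `p_value < alpha`.
#'
#' @param expr Numeric matrix (genes x samples), log2 scale, with gene
#'   rownames and sample colnames.
#' @param group_labels Character vector per sample, values `"stim"` /
#'   `"unstim"`; each group needs >= 2 samples.
#' @param lfc_threshold Log2 fold-change threshold (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   classical equal-variance Student's t-test (default `FALSE`).
#' @param normalize Quantile-normalize first (default `TRUE`).
#' @return A `data.frame` with `gene`, `log2_fold_change`, `p_value`,
#'   `inducible`.
#' @export
call_inducible_genes <- function(expr, group_labels, lfc_threshold = 1,
                                 alpha = 0.05, welch = FALSE,
                                 normalize = TRUE) {
  if (!all(group_labels %in% c("stim", "unstim"))) {
    stop("group_labels must be 'stim' or 'unstim'")
  }
  si <- which(group_labels == "stim")
  ui <- which(group_labels == "unstim")
  if (length(si) < 2 || length(ui) < 2) {
    stop("each group needs at least 2 samples")
  }
  m <- if (normalize) quantile_normalize(expr) else as.matrix(expr)
  lfc <- rowMeans(m[, si, drop = FALSE]) -
    rowMeans(m[, ui, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(g) {
    x <- m[g, si]; y <- m[g, ui]
    if (stats::sd(c(x, y)) == 0) return(1)
    # degenerate zero-within-variance genes: perfectly separated
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(0)
    stats::t.test(x, y, var.equal = !welch)$p.value
  }, numeric(1))
  data.frame(gene = rownames(m), log2_fold_change = lfc, p_value = p,
             inducible = lfc > lfc_threshold & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an expression matrix TSV (first column gene, header row samples)
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}
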