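# Binding-site occupancy and promoter signal dynamics: where does a
# chromatin factor sit (enhancer / promoter / other), how does that
# change with stimulation, and how does input-normalized promoter
# signal (e.g. H3K9me2) move between conditions.

#' Classify binding sites against enhancer and promoter universes
#'
#' Category precedence is promoter > enhancer > other: a site
#' overlapping a promoter window is `promoter` even if it also touches
#' an enhancer (the two universes are near-disjoint by construction,
#' since qualified enhancers exclude TSS-proximal peaks).
#'
#' @param sites Factor binding-site peak table (FDR-filtered upstream).
#' @param enhancers Qualified enhancer call table.
#' @param promoters Promoter windows from [promoter_regions()].
#' @return `sites` with `category` and `rank_by_score` (1 = highest
#'   score; ties broken by chromosome then start) appended.
#' @export
classify_binding_sites <- function(sites, enhancers, promoters) {
  enh <- enhancers[isTRUE_vec(enhancers$qualified), , drop = FALSE]
  in_prom <- overlaps_any(sites, promoters)
  in_enh <- overlaps_any(sites, enh)
  sites$category <- ifelse(in_prom, "promoter",
                           ifelse(in_enh, "enhancer", "other"))
  ord <- order(-sites$score, sites$chrom, sites$start)
  sites$rank_by_score <- NA_integer_
  sites$rank_by_score[ord] <- seq_len(nrow(sites))
  sites
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else x %in% TRUE

#' Select the top-n sites by score
#'
#' Ties at the cutoff break deterministically by (chromosome, start),
#' lower coordinates first, so re-running on a permuted input returns
#' an identical list.
#'
#' @param sites Peak table with a `score` column.
#' @param n Number of sites (>= 1). If fewer sites exist, all are
#'   returned with a warning.
#' @return The selected rows, in rank order.
#' @export
top_n_sites <- function(sites, n) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(sites) < n) {
    warning(sprintf("only %d sites available (requested %d)",
                    nrow(sites), n))
    n <- nrow(sites)
  }
  ord <- order(-sites$score, sites$chrom, sites$start)
  sites[ord[seq_len(n)], , drop = FALSE]
}

#' Colocalization fractions of classified binding sites
#'
#' @param annotations Output of [classify_binding_sites()] (non-empty).
#' @return Named numeric vector of percentages
#'   (`enhancer`, `promoter`, `other`), summing to 100.
#' @export
colocalization_fractions <- function(annotations) {
  if (nrow(annotations) == 0) stop("no annotated sites")
  cats <- c("enhancer", "promoter", "other")
  counts <- vapply(cats, function(k) sum(annotations$category == k),
                   numeric(1))
  100 * counts / nrow(annotations)
}

#' Stratify enhancers by factor binding
#'
#' @param enhancers Qualified enhancer calls with `activity_class`.
#' @param sites Binding-site peak table.
#' @return A list: `calls` (enhancers with logical `bound`),
#'   `fraction_overall` (percent bound) and `fraction_by_class` (named
#'   percent per activity class; `NA` for empty classes).
#' @export
stratify_enhancers_by_binding <- function(enhancers, sites) {
  enhancers$bound <- overlaps_any(enhancers, sites)
  classes <- c("active", "intermediate", "poised", "conflicted")
  by_class <- vapply(classes, function(k) {
    sel <- enhancers$activity_class %in% k
    if (!any(sel)) return(NA_real_)
    100 * mean(enhancers$bound[sel])
  }, numeric(1))
  list(calls = enhancers,
       fraction_overall = 100 * mean(enhancers$bound),
       fraction_by_class = by_class)
}

#' Input-normalized promoter signal
#'
#' Per promoter window, the mean RPM of the IP track and of the input
#' track, and their ratio with a symmetric pseudo-RPM epsilon:
#' `(ip + eps) / (input + eps)`.
#'
#' @param ip_track,input_track RPM `coverage_track`s, each normalized
#'   with its own library statistics.
#' @param promoters Promoter windows from [promoter_regions()].
#' @param epsilon Pseudo-RPM (default 0.01).
#' @param condition Label recorded on each row.
#' @return A `data.frame`: `gene`, `ip_rpm`, `input_rpm`, `ratio`,
#'   `condition`.
#' @export
promoter_signal_ratio <- function(ip_track, input_track, promoters,
                                  epsilon = 0.01,
                                  condition = NA_character_) {
  ip <- vapply(seq_len(nrow(promoters)), function(i) {
    window_mean(ip_track, promoters$chrom[i], promoters$start[i],
                promoters$end[i])
  }, numeric(1))
  inp <- vapply(seq_len(nrow(promoters)), function(i) {
    window_mean(input_track, promoters$chrom[i], promoters$start[i],
                promoters$end[i])
  }, numeric(1))
  data.frame(gene = promoters$gene, ip_rpm = ip, input_rpm = inp,
             ratio = (ip + epsilon) / (inp + epsilon),
             condition = condition, stringsAsFactors = FALSE)
}

#' Compare two sets of promoter signal records
#'
#' Unpaired (two-sample) or paired t-test on the `ratio` column; used
#' for inducible-vs-random, pre-vs-post and bound-vs-unbound
#' contrasts. Degenerate zero-variance comparisons report p = 1.
#'
#' @param records_a,records_b [promoter_signal_ratio()] outputs.
#' @param paired Paired test; requires identical gene vectors.
#' @return A list: `mean_a`, `mean_b`, `difference` (a - b),
#'   `p_value`, `n_a`, `n_b`, `paired`.
#' @export
compare_promoter_sets <- function(records_a, records_b, paired = FALSE) {
  if (nrow(records_a) < 2 || nrow(records_b) < 2) {
    stop("each set needs at least 2 records")
  }
  a <- records_a$ratio
  b <- records_b$ratio
  if (paired) {
    if (nrow(records_a) != nrow(records_b) ||
        !identical(records_a$gene, records_b$gene)) {
      stop("paired comparison requires matched gene lists")
    }
    d <- a - b
    p <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
  } else {
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      stats::t.test(a, b)$p.value
  }
  list(mean_a = mean(a), mean_b = mean(b),
       difference = mean(a) - mean(b), p_value = p,
       n_a = length(a), n_b = length(b), paired = paired)
}
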