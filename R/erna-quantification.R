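# Summit-anchored, strand-aware eRNA quantification. eRNAs are short
# (< 2 kb), bidirectional transcripts, so only fixed 2-kb windows
# flanking the p300 summit are quantified: + strand reads immediately
# downstream, - strand reads immediately upstream. Four exclusion
# filters remove loci that look like unannotated genes (strand ratio,
# flanking signal), repeats, or rRNA.

#' eRNA filter configuration
#'
#' @param ratio_threshold Strand-ratio threshold (default 5): a locus is
#'   excluded when (plus_down + pc) / (minus_up + pc) exceeds it.
#' @param ratio_pseudocount Pseudocount added to both strands' counts in
#'   the ratio (default 1 tag).
#' @param fpkm_repeat_threshold FPKM gate for the repeat filter
#'   (default 1).
#' @param symmetric_ratio Also exclude when the reciprocal ratio exceeds
#'   the threshold (default `FALSE`; the one-directional test is the
#'   canonical rule, the symmetric variant flags minus-strand-dominant
#'   loci as well).
#' @param window Proximal window size in bp (default 2000).
#' @return A list of class `erna_filter_config`.
#' @export
erna_filter_config <- function(ratio_threshold = 5, ratio_pseudocount = 1,
                               fpkm_repeat_threshold = 1,
                               symmetric_ratio = FALSE, window = 2000) {
  if (ratio_threshold <= 0 || ratio_pseudocount <= 0 ||
      fpkm_repeat_threshold <= 0 || window <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 ratio_pseudocount = ratio_pseudocount,
                 fpkm_repeat_threshold = fpkm_repeat_threshold,
                 symmetric_ratio = symmetric_ratio, window = window),
            class = "erna_filter_config")
}

#' Build eRNA loci around enhancer summits
#'
#' For each enhancer, counts strand-specific RNA tags (by 5' position)
#' in four windows around the summit s: plus-strand proximal
#' `[s, s+w)`, minus-strand proximal `[s-w, s)`, plus-strand far
#' `[s+w, s+2w)` and minus-strand far `[s-2w, s-w)`, with `w` the
#' configured window (2 kb). Windows are clamped to chromosome bounds
#' and the clamped lengths are used for FPKM.
#'
#' @param enhancers Enhancer call table (qualified, extragenic rows are
#'   the intended input); must carry `enhancer_id`, `chrom`, `summit`.
#' @param rna_tags Stranded RNA tag table (`chrom`, `start`, `end`,
#'   `strand`).
#' @param stats [library_stats()] of the RNA library.
#' @param layout [genome_layout()].
#' @param cfg [erna_filter_config()] (for the window size).
#' @return A `data.frame`, one row per enhancer: window counts
#'   (`plus_down`, `minus_up`, `plus_far`, `minus_far`), clamped window
#'   lengths, `fpkm_plus`, `fpkm_minus`, and placeholder `passed` /
#'   `exclusion_reasons` columns.
#' @export
build_erna_loci <- function(enhancers, rna_tags, stats, layout,
                            cfg = erna_filter_config()) {
  if (any(is.na(enhancers$summit))) {
    stop("every enhancer needs a resolvable summit")
  }
  w <- cfg$window
  len <- chrom_length(layout, enhancers$chrom)
  plus <- rna_tags[rna_tags$strand == "+", , drop = FALSE]
  minus <- rna_tags[rna_tags$strand == "-", , drop = FALSE]
  n <- nrow(enhancers)
  cnt <- function(tags, chrom, lo, hi) {
    vapply(seq_len(n), function(i) {
      count_tags_in_window(tags, chrom[i], lo[i], hi[i],
                           method = "five_prime")
    }, integer(1))
  }
  s <- enhancers$summit
  pd_lo <- pmax(0, s);        pd_hi <- pmin(s + w, len)
  mu_lo <- pmax(0, s - w);    mu_hi <- pmin(s, len)
  pf_lo <- pmax(0, s + w);    pf_hi <- pmin(s + 2 * w, len)
  mf_lo <- pmax(0, s - 2 * w); mf_hi <- pmin(s - w, len)
  out <- data.frame(
    enhancer_id = enhancers$enhancer_id,
    chrom = enhancers$chrom, summit = s,
    plus_down = cnt(plus, enhancers$chrom, pd_lo, pd_hi),
    minus_up = cnt(minus, enhancers$chrom, mu_lo, mu_hi),
    plus_far = cnt(plus, enhancers$chrom, pf_lo, pf_hi),
    minus_far = cnt(minus, enhancers$chrom, mf_lo, mf_hi),
    len_plus_down = pmax(pd_hi - pd_lo, 0),
    len_minus_up = pmax(mu_hi - mu_lo, 0),
    len_plus_far = pmax(pf_hi - pf_lo, 0),
    len_minus_far = pmax(mf_hi - mf_lo, 0),
    stringsAsFactors = FALSE)
  out$fpkm_plus <- region_fpkm(out$plus_down,
                               pmax(out$len_plus_down, 1), stats)
  out$fpkm_minus <- region_fpkm(out$minus_up,
                                pmax(out$len_minus_up, 1), stats)
  out$passed <- NA
  out$exclusion_reasons <- NA_character_
  out
}

#' Apply the eRNA exclusion filters
#'
#' Exclusion reasons, all evaluated (no short-circuit):
#' * `strand_ratio` — (plus_down + pc)/(minus_up + pc) >
#'   `ratio_threshold` (and the reciprocal too when `symmetric_ratio`);
#'   a strongly unidirectional locus looks like an unannotated gene.
#' * `flanking_signal` — more signal in the 2-4 kb far window than the
#'   proximal window on either strand (density per bp when clamping has
#'   made lengths unequal, raw counts otherwise); eRNAs are short, so
#'   hot flanks indicate a long/genic transcript.
#' * `repeat_signal` — the locus carries an external repeat flag and
#'   max(fpkm_plus, fpkm_minus) > `fpkm_repeat_threshold`.
#' * `rrna_homology` — any of the four windows overlaps the rRNA
#'   blacklist.
#'
#' @param loci Output of [build_erna_loci()].
#' @param cfg [erna_filter_config()].
#' @param rrna_blacklist Interval data.frame (may be empty or `NULL`).
#' @param repeat_flags Logical vector, one per locus (recycled if
#'   length 1), or `NULL` for all-`FALSE`.
#' @return `loci` with `passed` and `exclusion_reasons` set; a locus
#'   passes iff no reason applies. Idempotent.
#' @export
apply_erna_filters <- function(loci, cfg = erna_filter_config(),
                               rrna_blacklist = NULL,
                               repeat_flags = NULL) {
  n <- nrow(loci)
  pc <- cfg$ratio_pseudocount
  if (is.null(repeat_flags)) repeat_flags <- rep(FALSE, n)
  repeat_flags <- rep_len(repeat_flags, n)

  ratio <- (loci$plus_down + pc) / (loci$minus_up + pc)
  strand_ratio <- ratio > cfg$ratio_threshold
  if (cfg$symmetric_ratio) {
    strand_ratio <- strand_ratio |
      (loci$minus_up + pc) / (loci$plus_down + pc) > cfg$ratio_threshold
  }

  dens <- function(count, len) ifelse(len > 0, count / len, 0)
  equal_plus <- loci$len_plus_far == loci$len_plus_down
  equal_minus <- loci$len_minus_far == loci$len_minus_up
  plus_hot <- ifelse(equal_plus, loci$plus_far > loci$plus_down,
                     dens(loci$plus_far, loci$len_plus_far) >
                       dens(loci$plus_down, loci$len_plus_down))
  minus_hot <- ifelse(equal_minus, loci$minus_far > loci$minus_up,
                      dens(loci$minus_far, loci$len_minus_far) >
                        dens(loci$minus_up, loci$len_minus_up))
  flanking <- plus_hot | minus_hot

  repeat_sig <- repeat_flags &
    pmax(loci$fpkm_plus, loci$fpkm_minus) > cfg$fpkm_repeat_threshold

  w <- cfg$window
  span <- data.frame(chrom = loci$chrom,
                     start = pmax(0, loci$summit - 2 * w),
                     end = loci$summit + 2 * w)
  rrna <- overlaps_any(span, rrna_blacklist)

  reasons <- vapply(seq_len(n), function(i) {
    paste(c(if (strand_ratio[i]) "strand_ratio",
            if (flanking[i]) "flanking_signal",
            if (repeat_sig[i]) "repeat_signal",
            if (rrna[i]) "rrna_homology"), collapse = ",")
  }, character(1))
  loci$passed <- reasons == ""
  loci$exclusion_reasons <- reasons
  loci
}

#' eRNA induction ratios between two conditions
#'
#' Per matched locus, the ratio of stimulated to unstimulated total
#' eRNA FPKM (`fpkm_plus + fpkm_minus`, each condition quantified with
#' its own library statistics). The FPKM pseudocount floors the
#' denominator at 0.02, so ratios are always finite.
#'
#' @param loci_unstim,loci_stim Locus tables from [build_erna_loci()]
#'   for the two conditions; matched by `enhancer_id`.
#' @return A list: `per_locus` data.frame (`enhancer_id`,
#'   `fpkm_unstim`, `fpkm_stim`, `ratio`) and `median_ratio`.
#' @export
erna_induction <- function(loci_unstim, loci_stim) {
  i <- match(loci_unstim$enhancer_id, loci_stim$enhancer_id)
  if (anyNA(i)) {
    stop("unmatched loci: ",
         paste(loci_unstim$enhancer_id[is.na(i)], collapse = ", "))
  }
  stim <- loci_stim[i, , drop = FALSE]
  tot_u <- loci_unstim$fpkm_plus + loci_unstim$fpkm_minus
  tot_s <- stim$fpkm_plus + stim$fpkm_minus
  per <- data.frame(enhancer_id = loci_unstim$enhancer_id,
                    fpkm_unstim = tot_u, fpkm_stim = tot_s,
                    ratio = tot_s / tot_u, stringsAsFactors = FALSE)
  list(per_locus = per, median_ratio = stats::median(per$ratio))
}
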