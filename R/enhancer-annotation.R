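# Enhancer definition from p300 peaks. A p300 peak qualifies when it
# clears the caller-score gate, is depleted of promoter features
# (no H3K4me3 overlap in any condition, not near a TSS) and carries the
# enhancer mark H3K4me1. All failing criteria are recorded, never
# short-circuited, so decoys can be audited by reason.

#' Enhancer qualification rule configuration
#'
#' @param min_score Minimum peak-caller score (default 60).
#' @param refseq_tss_radius Exclusion radius around RefSeq-like TSSs in
#'   bp (default 1000): a peak closer than this is rejected.
#' @param est_tss_radius Exclusion radius around spliced-EST-like TSSs
#'   (default 2000).
#' @param tes_exclusion_radius Radius around transcription end sites
#'   within which an otherwise extragenic enhancer is set aside
#'   (default 5000), so that read-through polymerase signal does not
#'   contaminate enhancer profiles.
#' @return A list of class `enhancer_rule_config`.
#' @export
enhancer_rule_config <- function(min_score = 60, refseq_tss_radius = 1000,
                                 est_tss_radius = 2000,
                                 tes_exclusion_radius = 5000) {
  if (any(c(refseq_tss_radius, est_tss_radius, tes_exclusion_radius) < 0)) {
    stop("radii must be >= 0")
  }
  structure(list(min_score = min_score,
                 refseq_tss_radius = refseq_tss_radius,
                 est_tss_radius = est_tss_radius,
                 tes_exclusion_radius = tes_exclusion_radius),
            class = "enhancer_rule_config")
}

#' Qualify p300 peaks as enhancers
#'
#' A peak qualifies iff all five predicates hold: (1) score >=
#' `min_score`; (2) no bp overlap with any H3K4me3 peak from any
#' supplied condition; (3) distance to every RefSeq-like TSS >=
#' `refseq_tss_radius`; (4) distance to every EST-like TSS >=
#' `est_tss_radius`; (5) >= 1 bp overlap with an H3K4me1 peak from any
#' condition. Peaks on chromosomes absent from the gene annotation are
#' rejected with reason `unassignable`, since the TSS criteria cannot
#' be certified there.
#'
#' @param p300 p300 peak table (see [read_intervals()]).
#' @param h3k4me3 H3K4me3 peaks pooled across all conditions.
#' @param h3k4me1 H3K4me1 peaks pooled across all conditions; required.
#' @param genes Gene model table containing both `refseq_like` and (if
#'   available) `est_like` entries.
#' @param cfg [enhancer_rule_config()].
#' @return The peak table with columns added: `enhancer_id`,
#'   `qualified`, `rejection_reasons` (comma-separated, empty when
#'   qualified), `location_class`, `activity_class`, `epu_gene` (the
#'   last three `"unassigned"`/`NA` until set downstream).
#' @export
qualify_enhancers <- function(p300, h3k4me3, h3k4me1, genes,
                              cfg = enhancer_rule_config()) {
  if (is.null(h3k4me1)) {
    stop("H3K4me1 peak set is required to evaluate qualification")
  }
  n <- nrow(p300)
  calls <- p300
  calls$enhancer_id <- if ("name" %in% names(p300) &&
                           !anyDuplicated(p300$name)) p300$name else
    sprintf("enh_%05d", seq_len(n))

  has_est <- any(genes$source == "est_like")
  d_ref <- nearest_tss_distance(calls, genes, source = "refseq_like")
  d_est <- if (has_est) {
    nearest_tss_distance(calls, genes, source = "est_like")
  } else rep(Inf, n)

  fail <- list(
    low_score = calls$score < cfg$min_score,
    h3k4me3_overlap = overlaps_any(calls, h3k4me3),
    refseq_tss_proximity = d_ref < cfg$refseq_tss_radius,
    est_tss_proximity = d_est < cfg$est_tss_radius,
    no_h3k4me1 = !overlaps_any(calls, h3k4me1),
    unassignable = !(calls$chrom %in% genes$chrom)
  )
  reasons <- vapply(seq_len(n), function(i) {
    r <- names(fail)[vapply(fail, `[`, logical(1), i)]
    paste(r, collapse = ",")
  }, character(1))
  calls$qualified <- reasons == ""
  calls$rejection_reasons <- reasons
  calls$location_class <- ifelse(calls$qualified, "unassigned",
                                 NA_character_)
  calls$activity_class <- NA_character_
  calls$epu_gene <- NA_character_
  calls
}

#' Split qualified enhancers into intragenic and extragenic
#'
#' Intragenic: peak interval fully contained in some RefSeq-like
#' transcription unit. Otherwise extragenic, unless within
#' `tes_exclusion_radius` of any RefSeq-like TES, in which case the
#' call is set aside as `excluded_near_tes`.
#'
#' @param calls Output of [qualify_enhancers()] (only qualified rows
#'   are classified; others keep `location_class = NA`).
#' @param genes Gene model table.
#' @param cfg [enhancer_rule_config()].
#' @return `calls` with `location_class` filled in.
#' @export
split_location_class <- function(calls, genes,
                                 cfg = enhancer_rule_config()) {
  refseq <- genes[genes$source == "refseq_like", , drop = FALSE]
  qi <- which(calls$qualified)
  if (!length(qi)) return(calls)
  q <- calls[qi, , drop = FALSE]
  inside <- contained_in_any(q, refseq)
  d_tes <- point_distance(q, refseq$chrom, refseq$tes)
  cls <- ifelse(inside, "intragenic",
                ifelse(d_tes < cfg$tes_exclusion_radius,
                       "excluded_near_tes", "extragenic"))
  calls$location_class[qi] <- cls
  calls
}

#' Assign enhancer activity classes from acetylation/methylation peaks
#'
#' Active: overlaps the acetylation mark but not the repressive mark.
#' Poised: repressive only. Intermediate: neither. Conflicted: both
#' (surfaced, not silently resolved; excluded from class fractions by
#' downstream summaries). The default mark pair is H3K9ac/H3K9me3; an
#' H3K27ac/H3K27me3 classification uses the same engine with those peak
#' sets supplied instead.
#'
#' @param calls Qualified enhancer calls.
#' @param ac_peaks Acetylation peak table (H3K9ac or H3K27ac).
#' @param me_peaks Repressive-methylation peak table (H3K9me3 or
#'   H3K27me3).
#' @return `calls` with `activity_class` filled for qualified rows.
#' @export
assign_activity_class <- function(calls, ac_peaks, me_peaks) {
  qi <- which(calls$qualified)
  if (!length(qi)) return(calls)
  q <- calls[qi, , drop = FALSE]
  ac <- overlaps_any(q, ac_peaks)
  me <- overlaps_any(q, me_peaks)
  calls$activity_class[qi] <-
    ifelse(ac & me, "conflicted",
           ifelse(ac, "active", ifelse(me, "poised", "intermediate")))
  calls
}
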