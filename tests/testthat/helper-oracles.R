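# Independent brute-force oracles and tiny fixture builders. The
# oracles are deliberately naive (per-element loops, no interval
# libraries) so they share no code path with the implementation.

tiny_layout <- function(len = 1e6, n = 1) {
  genome_layout(sprintf("chrT%d", seq_len(n)), rep(len, n))
}

make_tags <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

make_intervals <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, score = 100,
                       summit = floor((start + end) / 2),
                       name = sprintf("pk_%04d", seq_along(start))) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = ".", summit = summit,
             mark = NA_character_, condition = NA_character_,
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, layout, max_width = 2000) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[match(chrom, layout$chrom)]
  width <- sample(seq_len(max_width), n, replace = TRUE)
  start <- floor(runif(n) * (len - width))
  make_intervals(chrom, start, start + width)
}

# O(n*m) loop oracle for half-open overlap.
brute_overlaps_any <- function(query, features) {
  sapply(seq_len(nrow(query)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(features))) {
      if (query$chrom[i] == features$chrom[j] &&
          query$start[i] < features$end[j] &&
          features$start[j] < query$end[i]) {
        hit <- TRUE
        break
      }
    }
    hit
  })
}

# Scan-over-all-genes oracle for interval-to-TSS distance.
brute_nearest_tss <- function(query, genes) {
  sapply(seq_len(nrow(query)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != query$chrom[i]) next
      tss <- genes$tss[j]
      d <- if (tss >= query$start[i] && tss < query$end[i]) 0
           else min(abs(tss - query$start[i]),
                    abs(tss - (query$end[i] - 1)),
                    abs(tss - query$end[i]))
      best <- min(best, d)
    }
    best
  })
}

# Per-peak re-evaluation of the five qualification predicates.
brute_qualify <- function(p300, h3k4me3, h3k4me1, genes, cfg) {
  ov <- function(i, feats) {
    any(feats$chrom == p300$chrom[i] & p300$start[i] < feats$end &
          feats$start < p300$end[i])
  }
  refs <- genes[genes$source == "refseq_like", ]
  ests <- genes[genes$source == "est_like", ]
  sapply(seq_len(nrow(p300)), function(i) {
    reasons <- character()
    if (p300$score[i] < cfg$min_score) reasons <- c(reasons, "low_score")
    if (ov(i, h3k4me3)) reasons <- c(reasons, "h3k4me3_overlap")
    d_ref <- brute_nearest_tss(p300[i, , drop = FALSE], refs)
    if (d_ref < cfg$refseq_tss_radius) {
      reasons <- c(reasons, "refseq_tss_proximity")
    }
    if (nrow(ests)) {
      d_est <- brute_nearest_tss(p300[i, , drop = FALSE], ests)
      if (d_est < cfg$est_tss_radius) {
        reasons <- c(reasons, "est_tss_proximity")
      }
    }
    if (!ov(i, h3k4me1)) reasons <- c(reasons, "no_h3k4me1")
    if (!(p300$chrom[i] %in% genes$chrom)) {
      reasons <- c(reasons, "unassignable")
    }
    paste(sort(reasons), collapse = ",")
  })
}

# Independent evaluation of the four eRNA exclusion predicates on a
# locus table (equal-length windows assumed, as in the fixtures).
brute_erna_reasons <- function(loci, cfg, blacklist, repeat_flags) {
  sapply(seq_len(nrow(loci)), function(i) {
    r <- character()
    if ((loci$plus_down[i] + cfg$ratio_pseudocount) /
          (loci$minus_up[i] + cfg$ratio_pseudocount) >
          cfg$ratio_threshold) {
      r <- c(r, "strand_ratio")
    }
    if (loci$plus_far[i] > loci$plus_down[i] ||
        loci$minus_far[i] > loci$minus_up[i]) {
      r <- c(r, "flanking_signal")
    }
    if (repeat_flags[i] &&
        max(loci$fpkm_plus[i], loci$fpkm_minus[i]) >
          cfg$fpkm_repeat_threshold) {
      r <- c(r, "repeat_signal")
    }
    if (!is.null(blacklist) && nrow(blacklist)) {
      lo <- loci$summit[i] - 2 * cfg$window
      hi <- loci$summit[i] + 2 * cfg$window
      if (any(blacklist$chrom == loci$chrom[i] & lo < blacklist$end &
                blacklist$start < hi)) {
        r <- c(r, "rrna_homology")
      }
    }
    paste(sort(r), collapse = ",")
  })
}

# Non-overlapping 2-kb windows for count-level differential tests.
win_acc <- function(n) {
  make_intervals(rep("chrW", n), (seq_len(n) - 1) * 2000,
                 seq_len(n) * 2000)
}

sorted_reasons <- function(x) {
  vapply(strsplit(x, ","), function(v) paste(sort(v), collapse = ","),
         character(1))
}

# Small simulation config used by module tests (fast; the default
# config is exercised by the acceptance tests).
small_sim_config <- function(seed = 7L) {
  simulation_config(
    seed = seed,
    chrom_lengths = c(chrA = 2.5e6, chrB = 2.5e6),
    n_refseq_plain = 10, n_est = 4,
    n_enhancers = c(active = 6, intermediate = 3, poised = 2),
    n_intragenic = 1, n_near_tes = 1,
    n_decoys = c(low_score = 1, h3k4me3_overlap = 1,
                 refseq_tss_proximity = 1, est_tss_proximity = 1,
                 no_h3k4me1 = 1),
    n_epu = c(assigned = 2, blocked = 1, out_of_range = 1),
    n_site_other = 4,
    n_erna_true = 4,
    n_erna_decoys = c(strand_ratio = 1, flanking_signal = 1,
                      repeat_signal = 1, rrna_homology = 1),
    me2_background = 2e4, input_depth = 1e5,
    n_sites_enhancer = 8, n_sites_promoter = 2, n_sites_other = 4,
    n_expr_genes = 200)
}
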