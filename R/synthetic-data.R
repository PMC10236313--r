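# Seed-deterministic generator of a miniature genome with planted
# enhancers, decoys, eRNA read clusters, CTCF blocks,
# condition-dependent ChIP signal and a two-condition expression
# matrix, together with a ground-truth manifest. Layout is slot-based:
# every planted element owns a fixed-width region, with spacing chosen
# so that no element accidentally violates another element's
# qualification radius. Expected outcomes are therefore computable
# from the configuration alone; Poisson rates are margin-safe so that
# no stochastic threshold crossing occurs at default settings.

SLOT <- 60000        # bp per planted element
TAG_LEN <- 36        # simulated read length

#' Simulation configuration
#'
#' Defaults define the package's reference fixture: a two-chromosome
#' 8 Mb genome, ~45 true enhancers across activity classes plus at
#' least two decoys per rejection class, bidirectional eRNA clusters
#' with one decoy class per exclusion filter, CTCF-delimited
#' enhancer-promoter-unit cases (assignable, insulator-blocked,
#' out-of-range), condition-dependent factor-binding-site
#' redistribution, promoter H3K9me2 depletion at inducible genes, and
#' a 1000-gene expression matrix with 10% planted induced genes.
#'
#' @param seed Integer seed; config + seed fully determine every
#'   output byte.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param n_refseq_plain Plain RefSeq-like genes (no hosted feature).
#' @param n_est Spliced-EST-like gene entries.
#' @param n_enhancers Named counts of true extragenic enhancers per
#'   activity class (`active`, `intermediate`, `poised`).
#' @param n_intragenic True enhancers contained in gene bodies.
#' @param n_near_tes Qualified enhancers within the TES exclusion zone.
#' @param n_decoys Named counts per qualification-rejection class.
#' @param n_epu Named counts of EPU cases (`assigned`, `blocked`,
#'   `out_of_range`); the EPU-case genes form the inducible gene set of
#'   the genome.
#' @param n_site_other Dedicated empty slots for `other`-category
#'   binding sites.
#' @param n_erna_true True bidirectional eRNA loci (planted on
#'   extragenic enhancers).
#' @param n_erna_decoys Named counts per eRNA exclusion class
#'   (`strand_ratio`, `flanking_signal`, `repeat_signal`,
#'   `rrna_homology`).
#' @param erna_rate Expected tags per strand in a proximal 2-kb window
#'   of a true eRNA locus.
#' @param erna_far_rate Expected tags per far window at true loci.
#' @param erna_induction_fold Fold increase of true-locus eRNA rates in
#'   the stimulated RNA library.
#' @param me2_promoter_rate Expected H3K9me2 IP tags per promoter
#'   window (TSS +/- 1 kb), unstimulated.
#' @param me2_depletion Multiplier on that rate at inducible promoters
#'   after stimulation (default 0.5, i.e. 2-fold loss).
#' @param me2_background,input_depth Uniform background tags for the
#'   H3K9me2 IP and input libraries.
#' @param ac_ctrl_rate Expected H4ac/H3K9ac tags per enhancer window,
#'   unstimulated.
#' @param ac_fold Fold enrichment at inducible enhancers on
#'   stimulation.
#' @param ac_background Uniform background tags per acetylation
#'   library.
#' @param n_sites_enhancer,n_sites_promoter,n_sites_other Planted
#'   factor-binding-site counts per category, unstimulated.
#' @param site_redistribution_fraction Fraction of enhancer-category
#'   sites relocated to inducible promoters after stimulation.
#' @param n_expr_genes,induced_fraction,induced_effect,expr_noise_sd,
#'   n_replicates Expression-matrix shape: genes, planted induced
#'   fraction, log2 effect size, Normal noise SD, replicates per group.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = c(chrSim1 = 4e6, chrSim2 = 4e6),
    n_refseq_plain = 30,
    n_est = 8,
    n_enhancers = c(active = 14, intermediate = 8, poised = 6),
    n_intragenic = 4,
    n_near_tes = 3,
    n_decoys = c(low_score = 2, h3k4me3_overlap = 2,
                 refseq_tss_proximity = 2, est_tss_proximity = 2,
                 no_h3k4me1 = 2),
    n_epu = c(assigned = 5, blocked = 3, out_of_range = 2),
    n_site_other = 10,
    n_erna_true = 12,
    n_erna_decoys = c(strand_ratio = 2, flanking_signal = 2,
                      repeat_signal = 2, rrna_homology = 2),
    erna_rate = 30,
    erna_far_rate = 2,
    erna_induction_fold = 2,
    me2_promoter_rate = 1000,
    me2_depletion = 0.5,
    me2_background = 2e5,
    input_depth = 1e6,
    ac_ctrl_rate = 60,
    ac_fold = 5,
    ac_background = 2e4,
    n_sites_enhancer = 35,
    n_sites_promoter = 5,
    n_sites_other = 10,
    site_redistribution_fraction = 0.2,
    n_expr_genes = 1000,
    induced_fraction = 0.1,
    induced_effect = 2,
    expr_noise_sd = 0.25,
    n_replicates = 3) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_refseq_plain = n_refseq_plain, n_est = n_est,
              n_enhancers = n_enhancers, n_intragenic = n_intragenic,
              n_near_tes = n_near_tes, n_decoys = n_decoys,
              n_epu = n_epu, n_site_other = n_site_other,
              n_erna_true = n_erna_true,
              n_erna_decoys = n_erna_decoys, erna_rate = erna_rate,
              erna_far_rate = erna_far_rate,
              erna_induction_fold = erna_induction_fold,
              me2_promoter_rate = me2_promoter_rate,
              me2_depletion = me2_depletion,
              me2_background = me2_background,
              input_depth = input_depth, ac_ctrl_rate = ac_ctrl_rate,
              ac_fold = ac_fold, ac_background = ac_background,
              n_sites_enhancer = n_sites_enhancer,
              n_sites_promoter = n_sites_promoter,
              n_sites_other = n_sites_other,
              site_redistribution_fraction = site_redistribution_fraction,
              n_expr_genes = n_expr_genes,
              induced_fraction = induced_fraction,
              induced_effect = induced_effect,
              expr_noise_sd = expr_noise_sd,
              n_replicates = n_replicates)
  counts <- unlist(cfg[c("n_refseq_plain", "n_est", "n_enhancers",
                         "n_intragenic", "n_near_tes", "n_decoys",
                         "n_epu", "n_site_other", "n_erna_true",
                         "n_erna_decoys")])
  if (any(counts < 0)) stop("feature counts must be >= 0")
  if (site_redistribution_fraction < 0 ||
      site_redistribution_fraction > 1) {
    stop("site_redistribution_fraction must be in [0, 1]")
  }
  if (induced_fraction < 0 || induced_fraction > 1) {
    stop("induced_fraction must be in [0, 1]")
  }
  if (n_replicates < 2) stop("need >= 2 replicates per group")
  n_extragenic <- sum(n_enhancers) + sum(n_epu)
  if (n_erna_true + sum(n_erna_decoys) > sum(n_enhancers)) {
    stop("eRNA loci (true + decoys) exceed available true extragenic ",
         "enhancers")
  }
  if (n_sites_enhancer > sum(n_enhancers) + n_intragenic + n_near_tes +
        sum(n_epu)) {
    stop("more enhancer-category sites requested than enhancers")
  }
  if (n_sites_promoter > n_refseq_plain) {
    stop("more promoter-category sites requested than plain genes")
  }
  structure(cfg, class = "sim_config")
}

# ---- layout plan ----------------------------------------------------

# One row per planted element; epu cases span several slots.
build_plan <- function(cfg) {
  el <- function(kind, subkind, n, slots = 1) {
    if (n == 0) return(NULL)
    data.frame(kind = kind, subkind = subkind,
               idx = seq_len(n), slots = slots,
               stringsAsFactors = FALSE)
  }
  ncl <- cfg$n_enhancers
  plan <- rbind(
    el("gene", "intragenic_host", cfg$n_intragenic),
    el("gene", "neartes_host", cfg$n_near_tes),
    el("gene", "tssdecoy_host", cfg$n_decoys[["refseq_tss_proximity"]]),
    el("gene", "plain", cfg$n_refseq_plain -
         cfg$n_decoys[["refseq_tss_proximity"]]),
    el("est", "estdecoy_host", cfg$n_decoys[["est_tss_proximity"]]),
    el("est", "plain", cfg$n_est -
         cfg$n_decoys[["est_tss_proximity"]]),
    el("enhancer", "active", ncl[["active"]]),
    el("enhancer", "intermediate", ncl[["intermediate"]]),
    el("enhancer", "poised", ncl[["poised"]]),
    el("decoy", "low_score", cfg$n_decoys[["low_score"]]),
    el("decoy", "h3k4me3_overlap", cfg$n_decoys[["h3k4me3_overlap"]]),
    el("decoy", "no_h3k4me1", cfg$n_decoys[["no_h3k4me1"]]),
    el("epu", "assigned", cfg$n_epu[["assigned"]], slots = 2),
    el("epu", "blocked", cfg$n_epu[["blocked"]], slots = 2),
    el("epu", "out_of_range", cfg$n_epu[["out_of_range"]], slots = 6),
    el("site_other", "other", cfg$n_site_other))
  if (cfg$n_refseq_plain < cfg$n_decoys[["refseq_tss_proximity"]] ||
      cfg$n_est < cfg$n_decoys[["est_tss_proximity"]]) {
    stop("not enough genes to host TSS-proximity decoys")
  }
  plan
}

# Assign each plan row a region start; fills chromosomes left to right.
place_plan <- function(plan, chrom_lengths) {
  chroms <- names(chrom_lengths)
  ci <- 1L
  cursor <- 0
  plan$chrom <- NA_character_
  plan$region_start <- NA_real_
  for (i in seq_len(nrow(plan))) {
    need <- plan$slots[i] * SLOT
    while (ci <= length(chroms) && cursor + need > chrom_lengths[ci]) {
      ci <- ci + 1L
      cursor <- 0
    }
    if (ci > length(chroms)) {
      stop("infeasible packing: planted features need ",
           sum(plan$slots) * SLOT, " bp but the genome has ",
           sum(chrom_lengths), " bp")
    }
    plan$chrom[i] <- chroms[ci]
    plan$region_start[i] <- cursor
    cursor <- cursor + need
  }
  plan
}

# ---- annotation -----------------------------------------------------

#' Simulate the genome annotation layer
#'
#' Places genes, EST entries, enhancers, decoys, CTCF sites and
#' binding-site slots on the configured genome with spacing larger
#' than every qualification radius, and records the expected outcome
#' of every downstream call in the truth tables.
#'
#' @param cfg [simulation_config()].
#' @return A list: `layout`, `genes` (RefSeq-like + EST-like models),
#'   `ctcf` (peak table), and `truth` (list of data.frames:
#'   `enhancers`, `genes`, `epu`).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  layout <- genome_layout(names(cfg$chrom_lengths), cfg$chrom_lengths)
  plan <- place_plan(build_plan(cfg), cfg$chrom_lengths)

  genes <- list(); ctcf_summits <- list(); enh <- list()
  gene_truth <- list(); epu_truth <- list()
  gi <- 0L; ei <- 0L; esti <- 0L
  plain_strand <- c("+", "-")

  add_gene <- function(chrom, start, end, strand, source, role,
                       inducible = FALSE) {
    if (source == "refseq_like") {
      gi <<- gi + 1L
      name <- sprintf("gene_%03d", gi)
    } else {
      esti <<- esti + 1L
      name <- sprintf("est_%03d", esti)
    }
    g <- gene_models(name, chrom, strand, start, end, source = source)
    genes[[length(genes) + 1L]] <<- g
    gene_truth[[length(gene_truth) + 1L]] <<- data.frame(
      gene = name, source = source, role = role, inducible = inducible,
      tss = g$tss, chrom = chrom, stringsAsFactors = FALSE)
    g
  }
  add_enh <- function(chrom, summit, score, subkind, expected_qualified,
                      expected_rejection, expected_location,
                      expected_activity, has_me1 = TRUE,
                      own_me3 = FALSE, inducible = FALSE,
                      host_gene = NA_character_) {
    ei <<- ei + 1L
    enh[[length(enh) + 1L]] <<- data.frame(
      name = sprintf("p300_%04d", ei), chrom = chrom,
      start = summit - 500, end = summit + 500, summit = summit,
      score = score, subkind = subkind,
      expected_qualified = expected_qualified,
      expected_rejection = expected_rejection,
      expected_location = expected_location,
      expected_activity = expected_activity, has_me1 = has_me1,
      own_me3 = own_me3, inducible = inducible, host_gene = host_gene,
      stringsAsFactors = FALSE)
  }
  true_score <- function() round(stats::runif(1, 80, 200), 1)

  for (i in seq_len(nrow(plan))) {
    r <- plan$region_start[i]
    ch <- plan$chrom[i]
    kind <- plan$kind[i]; sub <- plan$subkind[i]
    if (kind == "gene") {
      strand <- if (sub == "plain") plain_strand[1 + plan$idx[i] %% 2]
        else "+"
      g <- add_gene(ch, r + 5000, r + 15000, strand, "refseq_like",
                    role = sub)
      if (sub == "intragenic_host") {
        add_enh(ch, r + 10000, true_score(), "intragenic", TRUE, "",
                "intragenic", "intermediate", host_gene = g$name)
      } else if (sub == "neartes_host") {
        add_enh(ch, r + 18000, true_score(), "near_tes", TRUE, "",
                "excluded_near_tes", "intermediate", host_gene = g$name)
      } else if (sub == "tssdecoy_host") {
        add_enh(ch, r + 3700, true_score(), "decoy_refseq_tss", FALSE,
                "refseq_tss_proximity", NA, NA, host_gene = g$name)
      }
    } else if (kind == "est") {
      g <- add_gene(ch, r + 5000, r + 15000, "+", "est_like",
                    role = sub)
      if (sub == "estdecoy_host") {
        add_enh(ch, r + 3500, true_score(), "decoy_est_tss", FALSE,
                "est_tss_proximity", NA, NA, host_gene = g$name)
      }
    } else if (kind == "enhancer") {
      add_enh(ch, r + 30000, true_score(), sub, TRUE, "", "extragenic",
              sub)
    } else if (kind == "decoy") {
      if (sub == "low_score") {
        add_enh(ch, r + 30000, 59, "decoy_low_score", FALSE,
                "low_score", NA, NA)
      } else if (sub == "h3k4me3_overlap") {
        add_enh(ch, r + 30000, true_score(), "decoy_h3k4me3", FALSE,
                "h3k4me3_overlap", NA, NA, own_me3 = TRUE)
      } else {
        add_enh(ch, r + 30000, true_score(), "decoy_no_h3k4me1", FALSE,
                "no_h3k4me1", NA, NA, has_me1 = FALSE)
      }
    } else if (kind == "epu") {
      if (sub == "assigned") {
        ctcf_summits[[length(ctcf_summits) + 1L]] <-
          data.frame(chrom = ch, summit = c(r + 5000, r + 115000))
        g <- add_gene(ch, r + 60000, r + 70000, "+", "refseq_like",
                      role = "epu_assigned", inducible = TRUE)
        add_enh(ch, r + 30000, true_score(), "epu_assigned", TRUE, "",
                "extragenic", "active", inducible = TRUE)
        epu_truth[[length(epu_truth) + 1L]] <- data.frame(
          enhancer = sprintf("p300_%04d", ei), gene = g$name,
          expected_reason = "assigned_nearest_in_block",
          expected_distance = abs(g$tss - (r + 30000)),
          stringsAsFactors = FALSE)
      } else if (sub == "blocked") {
        ctcf_summits[[length(ctcf_summits) + 1L]] <-
          data.frame(chrom = ch,
                     summit = c(r + 5000, r + 45000, r + 115000))
        g <- add_gene(ch, r + 60000, r + 70000, "+", "refseq_like",
                      role = "epu_blocked", inducible = TRUE)
        add_enh(ch, r + 30000, true_score(), "epu_blocked", TRUE, "",
                "extragenic", "active", inducible = TRUE)
        epu_truth[[length(epu_truth) + 1L]] <- data.frame(
          enhancer = sprintf("p300_%04d", ei), gene = NA_character_,
          expected_reason = "no_tss_in_block",
          expected_distance = NA_real_, stringsAsFactors = FALSE)
      } else {
        ctcf_summits[[length(ctcf_summits) + 1L]] <-
          data.frame(chrom = ch, summit = c(r + 5000, r + 355000))
        g <- add_gene(ch, r + 280000, r + 290000, "+", "refseq_like",
                      role = "epu_out_of_range", inducible = TRUE)
        add_enh(ch, r + 30000, true_score(), "epu_out_of_range", TRUE,
                "", "extragenic", "active", inducible = TRUE)
        epu_truth[[length(epu_truth) + 1L]] <- data.frame(
          enhancer = sprintf("p300_%04d", ei), gene = NA_character_,
          expected_reason = "out_of_range",
          expected_distance = abs(g$tss - (r + 30000)),
          stringsAsFactors = FALSE)
      }
    }
    # site_other slots carry no annotation
  }

  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  ctcf <- if (length(ctcf_summits)) do.call(rbind, ctcf_summits) else
    data.frame(chrom = character(), summit = numeric())
  if (nrow(ctcf)) {
    ctcf <- data.frame(chrom = ctcf$chrom, start = ctcf$summit - 100,
                       end = ctcf$summit + 100,
                       name = sprintf("ctcf_%03d", seq_len(nrow(ctcf))),
                       score = 100, strand = ".",
                       summit = ctcf$summit, mark = "ctcf",
                       condition = "unstim", stringsAsFactors = FALSE)
  }
  enh <- do.call(rbind, enh)
  rownames(enh) <- NULL
  truth <- list(enhancers = enh,
                genes = do.call(rbind, gene_truth),
                epu = if (length(epu_truth)) do.call(rbind, epu_truth)
                      else NULL,
                plan = plan)
  list(layout = layout, genes = genes, ctcf = ctcf, truth = truth)
}

# ---- signal ---------------------------------------------------------

# n tags fully inside [lo, hi), random strand (ChIP-style, counted by
# midpoint downstream).
window_chip_tags <- function(n, chrom, lo, hi) {
  if (n == 0) return(NULL)
  start <- floor(stats::runif(n, lo, hi - TAG_LEN))
  data.frame(chrom = chrom, start = start, end = start + TAG_LEN,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# n stranded RNA tags whose 5' position is uniform in [lo, hi).
window_rna_tags <- function(n, chrom, lo, hi, strand) {
  if (n == 0) return(NULL)
  p5 <- floor(stats::runif(n, lo, hi))
  if (strand == "+") {
    data.frame(chrom = chrom, start = p5, end = p5 + TAG_LEN,
               strand = "+", stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = chrom, start = pmax(0, p5 + 1 - TAG_LEN),
               end = p5 + 1, strand = "-", stringsAsFactors = FALSE)
  }
}

uniform_tags <- function(n, layout, avoid = NULL) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  }
  probs <- layout$length / sum(layout$length)
  chrom <- sample(layout$chrom, n, replace = TRUE, prob = probs)
  len <- chrom_length(layout, chrom)
  start <- floor(stats::runif(n) * (len - TAG_LEN))
  out <- data.frame(chrom = chrom, start = start, end = start + TAG_LEN,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(avoid) && nrow(avoid)) {
    mid <- data.frame(chrom = out$chrom,
                      start = floor((out$start + out$end) / 2),
                      end = floor((out$start + out$end) / 2) + 1)
    out <- out[!overlaps_any(mid, avoid), , drop = FALSE]
  }
  out
}

sort_tags <- function(tags) {
  tags[order(tags$chrom, tags$start, tags$end, tags$strand), ,
       drop = FALSE]
}

# eRNA window rates per decoy class; margin-safe: each decoy trips
# exactly one filter with overwhelming probability.
erna_rates <- function(role, cfg) {
  switch(role,
    true = c(pd = cfg$erna_rate, mu = cfg$erna_rate,
             pf = cfg$erna_far_rate, mf = cfg$erna_far_rate),
    strand_ratio = c(pd = 150, mu = 5, pf = 0, mf = 0),
    flanking_signal = c(pd = 20, mu = 20, pf = 100, mf = 0),
    repeat_signal = c(pd = 150, mu = 150, pf = 0, mf = 0),
    rrna_homology = c(pd = cfg$erna_rate, mu = cfg$erna_rate,
                      pf = 0, mf = 0),
    silent = c(pd = 0, mu = 0, pf = 0, mf = 0))
}

#' Simulate peak files, tag libraries and binding sites
#'
#' Realizes the annotation's planted features as ChIP peaks, stranded
#' RNA tags, H3K9me2/input and acetylation tag libraries, and
#' condition-wise factor binding sites, per the configured rates.
#'
#' @param cfg [simulation_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list with `peaks` (named list of peak tables), `tags`
#'   (named list of tag tables), `sites` (`unstim`/`stim` peak
#'   tables), `blacklist`, `repeat_flags`, and `truth` additions
#'   (`erna`, `sites`, `me2`).
#' @export
simulate_chip_and_rna <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  layout <- ann$layout
  enh <- ann$truth$enhancers
  genes <- ann$genes

  # --- peaks -----------------------------------------------------
  mk_peak <- function(sel, half, mark, prefix) {
    e <- enh[sel, , drop = FALSE]
    if (!nrow(e)) return(empty_peaks(mark, "unstim"))
    data.frame(chrom = e$chrom, start = e$summit - half,
               end = e$summit + half,
               name = sprintf("%s_%04d", prefix, seq_len(nrow(e))),
               score = 100, strand = ".", summit = e$summit,
               mark = mark, condition = "unstim",
               stringsAsFactors = FALSE)
  }
  p300 <- data.frame(chrom = enh$chrom, start = enh$start,
                     end = enh$end, name = enh$name, score = enh$score,
                     strand = ".", summit = enh$summit, mark = "p300",
                     condition = "unstim", stringsAsFactors = FALSE)
  me1 <- mk_peak(enh$has_me1, 1000, "h3k4me1", "me1")
  # promoter H3K4me3 at every RefSeq-like gene
  ref <- genes[genes$source == "refseq_like", , drop = FALSE]
  me3 <- data.frame(chrom = ref$chrom, start = ref$tss - 500,
                    end = ref$tss + 500,
                    name = sprintf("me3_%04d", seq_len(nrow(ref))),
                    score = 100, strand = ".", summit = ref$tss,
                    mark = "h3k4me3", condition = "unstim",
                    stringsAsFactors = FALSE)
  me3 <- rbind(me3, mk_peak(enh$own_me3, 300, "h3k4me3", "me3d"))
  active <- enh$expected_activity %in% "active"
  poised <- enh$expected_activity %in% "poised"
  h3k9ac <- mk_peak(active, 400, "h3k9ac", "k9ac")
  h3k9me3 <- mk_peak(poised, 600, "h3k9me3", "k9me3")
  h3k27ac <- mk_peak(active, 400, "h3k27ac", "k27ac")
  h3k27me3 <- mk_peak(poised, 600, "h3k27me3", "k27me3")

  # --- eRNA role assignment and RNA libraries --------------------
  extr_true <- which(enh$expected_location %in% "extragenic" &
                       !startsWith(enh$subkind, "epu"))
  roles <- rep("silent", nrow(enh))
  stopifnot(length(extr_true) >=
              cfg$n_erna_true + sum(cfg$n_erna_decoys))
  k <- 0L
  roles[extr_true[seq_len(cfg$n_erna_true)]] <- "true"
  k <- cfg$n_erna_true
  for (cls in names(cfg$n_erna_decoys)) {
    n <- cfg$n_erna_decoys[[cls]]
    if (n > 0) roles[extr_true[k + seq_len(n)]] <- cls
    k <- k + n
  }
  erna_role <- ifelse(seq_len(nrow(enh)) %in% extr_true |
                        startsWith(enh$subkind, "epu"),
                      roles, NA)
  erna_role[startsWith(enh$subkind, "epu")] <- "silent"

  rna_lib <- function(fold_true) {
    pieces <- list()
    w <- 2000
    for (i in seq_len(nrow(enh))) {
      role <- erna_role[i]
      if (is.na(role) || role == "silent") next
      r <- erna_rates(role, cfg)
      if (role == "true") r[c("pd", "mu")] <- r[c("pd", "mu")] * fold_true
      s <- enh$summit[i]; ch <- enh$chrom[i]
      pieces[[length(pieces) + 1L]] <- rbind(
        window_rna_tags(stats::rpois(1, r[["pd"]]), ch, s, s + w, "+"),
        window_rna_tags(stats::rpois(1, r[["mu"]]), ch, s - w, s, "-"),
        window_rna_tags(stats::rpois(1, r[["pf"]]), ch, s + w,
                        s + 2 * w, "+"),
        window_rna_tags(stats::rpois(1, r[["mf"]]), ch, s - 2 * w,
                        s - w, "-"))
    }
    sort_tags(do.call(rbind, pieces))
  }
  rna_unstim <- rna_lib(1)
  rna_stim <- rna_lib(cfg$erna_induction_fold)

  blacklist_sel <- which(erna_role %in% "rrna_homology")
  blacklist <- data.frame(chrom = enh$chrom[blacklist_sel],
                          start = enh$summit[blacklist_sel] - 500,
                          end = enh$summit[blacklist_sel] + 500,
                          stringsAsFactors = FALSE)
  repeat_flags <- data.frame(enhancer_id = enh$name,
                             repeat_flag = erna_role %in% "repeat_signal",
                             stringsAsFactors = FALSE)

  erna_truth <- data.frame(
    enhancer_id = enh$name, role = erna_role,
    expected_pass = ifelse(is.na(erna_role), NA,
                           erna_role %in% c("true", "silent")),
    expected_reason = ifelse(erna_role %in% c("true", "silent") |
                               is.na(erna_role), "", erna_role),
    stringsAsFactors = FALSE)

  # --- H3K9me2 / input libraries ---------------------------------
  ref_truth <- ann$truth$genes[ann$truth$genes$source == "refseq_like", ]
  prom <- promoter_regions(
    genes[match(ref_truth$gene, genes$name), , drop = FALSE],
    half_width = 1000, layout = layout)
  me2_lib <- function(stim) {
    pieces <- lapply(seq_len(nrow(prom)), function(i) {
      rate <- cfg$me2_promoter_rate
      if (stim && ref_truth$inducible[i]) rate <- rate * cfg$me2_depletion
      window_chip_tags(stats::rpois(1, rate), prom$chrom[i],
                       prom$start[i], prom$end[i])
    })
    planted <- do.call(rbind, pieces)
    bg <- uniform_tags(cfg$me2_background, layout, avoid = prom)
    sort_tags(rbind(planted, bg))
  }
  me2_unstim <- me2_lib(FALSE)
  me2_stim <- me2_lib(TRUE)
  input_unstim <- sort_tags(uniform_tags(cfg$input_depth, layout))
  input_stim <- sort_tags(uniform_tags(cfg$input_depth, layout))
  me2_truth <- data.frame(
    gene = ref_truth$gene, inducible = ref_truth$inducible,
    expected_post_pre_ratio = ifelse(ref_truth$inducible,
                                     cfg$me2_depletion, 1),
    stringsAsFactors = FALSE)

  # --- acetylation libraries for inducible-enhancer calling ------
  qual <- which(enh$expected_qualified)
  ac_lib <- function(stim) {
    pieces <- lapply(qual, function(i) {
      rate <- cfg$ac_ctrl_rate
      if (stim && enh$inducible[i]) rate <- rate * cfg$ac_fold
      window_chip_tags(stats::rpois(1, rate), enh$chrom[i],
                       enh$summit[i] - 1000, enh$summit[i] + 1000)
    })
    planted <- do.call(rbind, pieces)
    bg <- uniform_tags(cfg$ac_background, layout)
    sort_tags(rbind(planted, bg))
  }
  h4ac_unstim <- ac_lib(FALSE); h4ac_stim <- ac_lib(TRUE)
  k9ac_unstim <- ac_lib(FALSE); k9ac_stim <- ac_lib(TRUE)

  # --- factor binding sites --------------------------------------
  mk_sites <- function(enh_idx, prom_genes, other_regions, condition) {
    rows <- list()
    if (length(enh_idx)) {
      rows[[1]] <- data.frame(
        chrom = enh$chrom[enh_idx], start = enh$summit[enh_idx] - 250,
        end = enh$summit[enh_idx] + 250,
        score = round(stats::runif(length(enh_idx), 100, 200), 1),
        category = "enhancer", stringsAsFactors = FALSE)
    }
    if (length(prom_genes)) {
      tss <- ref_truth$tss[match(prom_genes, ref_truth$gene)]
      ch <- ref_truth$chrom[match(prom_genes, ref_truth$gene)]
      rows[[2]] <- data.frame(
        chrom = ch, start = tss - 200, end = tss + 200,
        score = round(stats::runif(length(prom_genes), 50, 100), 1),
        category = "promoter", stringsAsFactors = FALSE)
    }
    if (nrow(other_regions)) {
      rows[[3]] <- data.frame(
        chrom = other_regions$chrom, start = other_regions$pos - 250,
        end = other_regions$pos + 250,
        score = round(stats::runif(nrow(other_regions), 50, 100), 1),
        category = "other", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    out$name <- sprintf("site_%s_%04d", condition, seq_len(nrow(out)))
    out$strand <- "."
    out$summit <- floor((out$start + out$end) / 2)
    out$mark <- "factor"; out$condition <- condition
    rownames(out) <- NULL
    out
  }
  other_slots <- ann$truth$plan[ann$truth$plan$kind == "site_other", ,
                                drop = FALSE]
  other_regions <- data.frame(chrom = other_slots$chrom,
                              pos = other_slots$region_start + 30000)
  enh_site_idx <- qual[seq_len(cfg$n_sites_enhancer)]
  plain_genes <- ref_truth$gene[ref_truth$role == "plain"]
  prom_site_genes <- plain_genes[seq_len(cfg$n_sites_promoter)]
  other_use <- other_regions[seq_len(min(cfg$n_sites_other,
                                         nrow(other_regions))), ,
                             drop = FALSE]
  sites_unstim <- mk_sites(enh_site_idx, prom_site_genes, other_use,
                           "unstim")
  n_move <- round(cfg$site_redistribution_fraction *
                    cfg$n_sites_enhancer)
  inducible_genes <- ref_truth$gene[ref_truth$inducible]
  if (n_move > length(inducible_genes)) {
    stop("site redistribution needs more inducible promoters than exist")
  }
  sites_stim <- mk_sites(
    enh_site_idx[seq_len(cfg$n_sites_enhancer - n_move)],
    c(prom_site_genes, inducible_genes[seq_len(n_move)]),
    other_use, "stim")

  comp <- function(s) {
    100 * c(enhancer = sum(s$category == "enhancer"),
            promoter = sum(s$category == "promoter"),
            other = sum(s$category == "other")) / nrow(s)
  }
  sites_truth <- list(unstim = comp(sites_unstim),
                      stim = comp(sites_stim))

  list(
    peaks = list(p300 = p300, h3k4me1 = me1, h3k4me3 = me3,
                 h3k9ac = h3k9ac, h3k9me3 = h3k9me3,
                 h3k27ac = h3k27ac, h3k27me3 = h3k27me3,
                 ctcf = ann$ctcf),
    tags = list(rna_unstim = rna_unstim, rna_stim = rna_stim,
                h3k9me2_unstim = me2_unstim, h3k9me2_stim = me2_stim,
                input_unstim = input_unstim, input_stim = input_stim,
                h4ac_unstim = h4ac_unstim, h4ac_stim = h4ac_stim,
                h3k9ac_unstim = k9ac_unstim, h3k9ac_stim = k9ac_stim),
    sites = list(unstim = sites_unstim, stim = sites_stim),
    blacklist = blacklist, repeat_flags = repeat_flags,
    truth = list(erna = erna_truth, sites = sites_truth,
                 me2 = me2_truth))
}

#' Simulate a two-condition expression matrix
#'
#' Log2-scale intensities with per-gene Normal(8, 2) baselines (a
#' spread typical of log2 array intensities, wide relative to the
#' planted effect so quantile normalization does not saturate it),
#' per-replicate Normal noise, and a planted log2 effect for the
#' induced set. The
#' genome's inducible genes are always part of the induced set; filler
#' genes complete it to the configured fraction.
#'
#' @param cfg [simulation_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list: `matrix` (genes x samples), `group_labels`, and
#'   `truth` data.frame (`gene`, `induced`).
#' @export
simulate_expression <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  genome_genes <- ann$truth$genes$gene[
    ann$truth$genes$source == "refseq_like"]
  inducible <- ann$truth$genes$gene[
    ann$truth$genes$source == "refseq_like" & ann$truth$genes$inducible]
  n_fill <- cfg$n_expr_genes - length(genome_genes)
  if (n_fill < 0) stop("n_expr_genes smaller than the genome gene set")
  fillers <- sprintf("xgene_%04d", seq_len(n_fill))
  all_genes <- c(genome_genes, fillers)
  n_ind <- round(cfg$induced_fraction * cfg$n_expr_genes)
  if (n_ind < length(inducible)) {
    stop("induced_fraction too small to cover the genome's inducible ",
         "genes")
  }
  induced <- c(inducible, fillers[seq_len(n_ind - length(inducible))])
  nr <- cfg$n_replicates
  samples <- c(sprintf("unstim_%d", seq_len(nr)),
               sprintf("stim_%d", seq_len(nr)))
  groups <- rep(c("unstim", "stim"), each = nr)
  base <- stats::rnorm(length(all_genes), 8, 2)
  m <- matrix(stats::rnorm(length(all_genes) * 2 * nr, mean = base,
                           sd = cfg$expr_noise_sd),
              nrow = length(all_genes), ncol = 2 * nr,
              dimnames = list(all_genes, samples))
  eff <- ifelse(all_genes %in% induced, cfg$induced_effect, 0)
  m[, groups == "stim"] <- m[, groups == "stim"] + eff
  list(matrix = m, group_labels = groups,
       truth = data.frame(gene = all_genes,
                          induced = all_genes %in% induced,
                          stringsAsFactors = FALSE))
}

# ---- file emission --------------------------------------------------

#' Generate the full synthetic dataset on disk
#'
#' Writes chrom.sizes, gene tables, peak files (narrowPeak for p300,
#' BED6 for the rest), tagAlign libraries, binding-site BEDs, the
#' expression matrix, the rRNA blacklist, per-locus repeat flags, the
#' ground-truth manifest tables (under `truth/`) and the resolved
#' configuration (`config.yaml`). Identical config + seed produce a
#' byte-identical directory.
#'
#' @param cfg [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `cfg`, `dir`, the in-memory `ann`,
#'   `sig`, `expr` objects and a named vector of file `paths`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  sig <- simulate_chip_and_rna(cfg, ann)
  expr <- simulate_expression(cfg, ann)

  p <- function(...) file.path(dir, ...)
  paths <- c(chrom_sizes = p("chrom.sizes"),
             genes_refseq = p("genes_refseq.tsv"),
             genes_est = p("genes_est.tsv"),
             p300 = p("peaks_p300.narrowPeak"),
             blacklist = p("blacklist_rrna.bed"),
             repeat_flags = p("repeat_flags.tsv"),
             expression = p("expression.tsv"),
             config = p("config.yaml"))
  data.table::fwrite(
    data.frame(ann$layout$chrom,
               format(ann$layout$length, scientific = FALSE,
                      trim = TRUE)),
    paths[["chrom_sizes"]], sep = "\t", col.names = FALSE,
    quote = FALSE)
  write_gene_table(ann$genes[ann$genes$source == "refseq_like", ],
                   paths[["genes_refseq"]])
  write_gene_table(ann$genes[ann$genes$source == "est_like", ],
                   paths[["genes_est"]])

  # p300 as 10-column narrowPeak (summit offset in column 10)
  p300 <- sig$peaks$p300
  np <- data.frame(p300$chrom,
                   format(p300$start, scientific = FALSE, trim = TRUE),
                   format(p300$end, scientific = FALSE, trim = TRUE),
                   p300$name, p300$score, ".", 0, -1, -1,
                   format(p300$summit - p300$start, scientific = FALSE,
                          trim = TRUE))
  data.table::fwrite(np, paths[["p300"]], sep = "\t",
                     col.names = FALSE, quote = FALSE)

  for (mk in c("h3k4me1", "h3k4me3", "h3k9ac", "h3k9me3", "h3k27ac",
               "h3k27me3", "ctcf")) {
    paths[[paste0("peaks_", mk)]] <- p(sprintf("peaks_%s.bed", mk))
    write_bed6(sig$peaks[[mk]], paths[[paste0("peaks_", mk)]])
  }
  for (cond in c("unstim", "stim")) {
    paths[[paste0("sites_", cond)]] <- p(sprintf("sites_%s.bed", cond))
    write_bed6(sig$sites[[cond]], paths[[paste0("sites_", cond)]])
  }
  for (lib in names(sig$tags)) {
    paths[[paste0("tags_", lib)]] <- p(sprintf("tags_%s.tagAlign", lib))
    write_tags(sig$tags[[lib]], paths[[paste0("tags_", lib)]])
  }
  if (nrow(sig$blacklist)) {
    write_bed6(sig$blacklist, paths[["blacklist"]])
  } else {
    file.create(paths[["blacklist"]])
  }
  data.table::fwrite(sig$repeat_flags, paths[["repeat_flags"]],
                     sep = "\t", quote = FALSE)

  em <- data.frame(gene = rownames(expr$matrix),
                   round(expr$matrix, 4), check.names = FALSE)
  data.table::fwrite(em, paths[["expression"]], sep = "\t",
                     quote = FALSE)

  truth_tabs <- list(enhancers = ann$truth$enhancers,
                     genes = ann$truth$genes, epu = ann$truth$epu,
                     erna = sig$truth$erna, me2 = sig$truth$me2,
                     expression = expr$truth)
  for (nm in names(truth_tabs)) {
    if (is.null(truth_tabs[[nm]])) next
    paths[[paste0("truth_", nm)]] <- p("truth", paste0(nm, ".tsv"))
    data.table::fwrite(truth_tabs[[nm]], paths[[paste0("truth_", nm)]],
                       sep = "\t", quote = FALSE)
  }
  comp <- rbind(data.frame(condition = "unstim",
                           t(sig$truth$sites$unstim)),
                data.frame(condition = "stim",
                           t(sig$truth$sites$stim)))
  paths[["truth_site_composition"]] <- p("truth",
                                         "site_composition.tsv")
  data.table::fwrite(comp, paths[["truth_site_composition"]],
                     sep = "\t", quote = FALSE)

  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(list(cfg = cfg, dir = dir, ann = ann, sig = sig,
                 expr = expr, paths = paths))
}
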