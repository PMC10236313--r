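# End-to-end orchestration over a dataset directory laid out as
# simulate_dataset() writes it (the same dialects any external dataset
# can be shaped into): enhancer annotation -> eRNA -> inducible sets ->
# EPU assignment -> occupancy and promoter dynamics -> report. The run
# is fully deterministic given the inputs and parameters; the log
# records parameters and input checksums but no timestamps, so
# identical runs produce byte-identical output trees.

#' Pipeline parameters
#'
#' @param enhancer_rules [enhancer_rule_config()].
#' @param erna_filters [erna_filter_config()].
#' @param fdr BH FDR threshold for differential enrichment
#'   (default 0.1).
#' @param promoter_half_width Promoter window half-width in bp
#'   (default 1000).
#' @param epu_max_range EPU assignment distance cap in bp
#'   (default 200000).
#' @param extension Tag 3' extension in bp (default 100).
#' @param bin_size Coverage bin size in bp (default 100).
#' @param top_n Top-site list size (default 1000; capped at the number
#'   of sites).
#' @param dedup_threshold Duplication rate above which a tag library is
#'   deduplicated (default 0.3).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(enhancer_rules = enhancer_rule_config(),
                            erna_filters = erna_filter_config(),
                            fdr = 0.1, promoter_half_width = 1000,
                            epu_max_range = 200000, extension = 100,
                            bin_size = 100, top_n = 1000,
                            dedup_threshold = 0.3) {
  structure(list(enhancer_rules = enhancer_rules,
                 erna_filters = erna_filters, fdr = fdr,
                 promoter_half_width = promoter_half_width,
                 epu_max_range = epu_max_range, extension = extension,
                 bin_size = bin_size, top_n = top_n,
                 dedup_threshold = dedup_threshold),
            class = "pipeline_params")
}

pipeline_files <- function(data_dir) {
  f <- function(...) file.path(data_dir, ...)
  list(chrom_sizes = f("chrom.sizes"),
       genes_refseq = f("genes_refseq.tsv"),
       genes_est = f("genes_est.tsv"),
       p300 = f("peaks_p300.narrowPeak"),
       h3k4me1 = f("peaks_h3k4me1.bed"),
       h3k4me3 = f("peaks_h3k4me3.bed"),
       h3k9ac = f("peaks_h3k9ac.bed"),
       h3k9me3 = f("peaks_h3k9me3.bed"),
       ctcf = f("peaks_ctcf.bed"),
       sites_unstim = f("sites_unstim.bed"),
       sites_stim = f("sites_stim.bed"),
       rna_unstim = f("tags_rna_unstim.tagAlign"),
       rna_stim = f("tags_rna_stim.tagAlign"),
       me2_unstim = f("tags_h3k9me2_unstim.tagAlign"),
       me2_stim = f("tags_h3k9me2_stim.tagAlign"),
       input_unstim = f("tags_input_unstim.tagAlign"),
       input_stim = f("tags_input_stim.tagAlign"),
       h4ac_unstim = f("tags_h4ac_unstim.tagAlign"),
       h4ac_stim = f("tags_h4ac_stim.tagAlign"),
       h3k9ac_unstim = f("tags_h3k9ac_unstim.tagAlign"),
       h3k9ac_stim = f("tags_h3k9ac_stim.tagAlign"),
       blacklist = f("blacklist_rrna.bed"),
       repeat_flags = f("repeat_flags.tsv"),
       expression = f("expression.tsv"))
}

# Dedup (if warranted), extend, bin, RPM — the canonical track recipe.
tags_to_rpm_track <- function(tags, layout, params) {
  dd <- deduplicate_tags(tags)
  if (dd$duplication_rate > params$dedup_threshold) tags <- dd$tags
  stats <- library_stats(max(nrow(tags), 1), dd$duplication_rate)
  ext <- extend_tags(tags, params$extension, layout)
  track <- bin_counts(ext, layout, bin_size = params$bin_size)
  rpm_normalize(track, stats)
}

#' Run the full analysis pipeline
#'
#' Validates that every input file exists, runs all stages, and writes
#' stage outputs, a `summary.json` report, and a parameter/checksum
#' log (`run.log`) to `out_dir`. A stage failure aborts with the stage
#' named and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param data_dir Dataset directory in the layout of
#'   [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param params [pipeline_params()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(data_dir, out_dir,
                         params = pipeline_params()) {
  files <- pipeline_files(data_dir)
  missing <- !vapply(files, file.exists, logical(1))
  if (any(missing)) {
    stop("missing input file(s): ",
         paste(unlist(files[missing]), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("ernascope pipeline run",
                 "parameters:",
                 paste0("  ", utils::capture.output(utils::str(
                   unclass(params), give.attr = FALSE))),
                 "input checksums (md5):",
                 sprintf("  %s  %s", tools::md5sum(unlist(files)),
                         basename(unlist(files))))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(log_lines, paste0("FAILED at stage: ", stage),
                 conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  summary <- tryCatch({
    stage <- "load"
    layout <- read_chrom_sizes(files$chrom_sizes)
    genes <- rbind(
      read_gene_table(files$genes_refseq, "refseq_like", layout),
      read_gene_table(files$genes_est, "est_like", layout))
    p300 <- read_intervals(files$p300, "narrowPeak", mark = "p300",
                           layout = layout)
    pk <- function(nm) read_intervals(files[[nm]], "bed6", mark = nm,
                                      layout = layout)

    stage <- "enhancers"
    calls <- qualify_enhancers(p300, pk("h3k4me3"), pk("h3k4me1"),
                               genes, params$enhancer_rules)
    calls <- split_location_class(calls, genes,
                                  params$enhancer_rules)
    calls <- assign_activity_class(calls, pk("h3k9ac"), pk("h3k9me3"))
    qualified <- calls[calls$qualified, , drop = FALSE]
    extragenic <- qualified[qualified$location_class == "extragenic", ,
                            drop = FALSE]
    write_bed6(data.frame(chrom = qualified$chrom,
                          start = qualified$start,
                          end = qualified$end,
                          name = qualified$enhancer_id,
                          score = qualified$score, strand = "."),
               file.path(out_dir, "enhancers_qualified.bed"))

    stage <- "erna"
    rna_u <- read_tags(files$rna_unstim, layout)
    rna_s <- read_tags(files$rna_stim, layout)
    stats_u <- library_stats(max(nrow(rna_u), 1))
    stats_s <- library_stats(max(nrow(rna_s), 1))
    blk <- if (file.size(files$blacklist) > 0) {
      read_intervals(files$blacklist, "auto")
    } else NULL
    rflags <- data.table::fread(files$repeat_flags)
    loci_u <- build_erna_loci(extragenic, rna_u, stats_u, layout,
                              params$erna_filters)
    flag_vec <- rflags$repeat_flag[match(loci_u$enhancer_id,
                                         rflags$enhancer_id)]
    flag_vec[is.na(flag_vec)] <- FALSE
    loci_u <- apply_erna_filters(loci_u, params$erna_filters, blk,
                                 flag_vec)
    loci_s <- build_erna_loci(extragenic, rna_s, stats_s, layout,
                              params$erna_filters)
    loci_s <- apply_erna_filters(loci_s, params$erna_filters, blk,
                                 flag_vec)
    passed_u <- loci_u[loci_u$passed, , drop = FALSE]
    induction <- erna_induction(passed_u,
                                loci_s[loci_s$enhancer_id %in%
                                         passed_u$enhancer_id, ,
                                       drop = FALSE])
    data.table::fwrite(loci_u, file.path(out_dir, "erna_loci.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(induction$per_locus,
                       file.path(out_dir, "erna_induction.tsv"),
                       sep = "\t", quote = FALSE)

    stage <- "inducible_genes"
    expr <- read_expression_matrix(files$expression)
    groups <- ifelse(startsWith(colnames(expr), "stim"), "stim",
                     "unstim")
    gene_calls <- call_inducible_genes(expr, groups)
    data.table::fwrite(gene_calls,
                       file.path(out_dir, "inducible_genes.tsv"),
                       sep = "\t", quote = FALSE)

    stage <- "inducible_enhancers"
    test_windows <- data.frame(chrom = qualified$chrom,
                               start = pmax(0, qualified$start - 500),
                               end = qualified$end + 500,
                               enhancer_id = qualified$enhancer_id,
                               stringsAsFactors = FALSE)
    diff_mark <- function(stim_file, ctrl_file) {
      ts <- read_tags(stim_file, layout)
      tc <- read_tags(ctrl_file, layout)
      window_differential_test(test_windows, ts, tc,
                               library_stats(max(nrow(ts), 1)),
                               library_stats(max(nrow(tc), 1)),
                               fdr = params$fdr)
    }
    h4ac_res <- diff_mark(files$h4ac_stim, files$h4ac_unstim)
    k9ac_res <- diff_mark(files$h3k9ac_stim, files$h3k9ac_unstim)
    calls <- call_inducible_enhancers(calls, h4ac_res, k9ac_res)
    data.table::fwrite(calls, file.path(out_dir, "enhancer_calls.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(h4ac_res,
                       file.path(out_dir, "differential_h4ac.tsv"),
                       sep = "\t", quote = FALSE)
    data.table::fwrite(k9ac_res,
                       file.path(out_dir, "differential_h3k9ac.tsv"),
                       sep = "\t", quote = FALSE)

    stage <- "epu"
    ctcf <- pk("ctcf")
    blocks <- partition_by_ctcf(ctcf, layout)
    inducible_names <- gene_calls$gene[gene_calls$inducible]
    target_genes <- genes[genes$name %in% inducible_names &
                            genes$source == "refseq_like", ,
                          drop = FALSE]
    epu <- if (nrow(target_genes)) {
      assign_enhancers_to_genes(extragenic, target_genes, blocks,
                                params$epu_max_range)
    } else NULL
    if (!is.null(epu)) {
      data.table::fwrite(epu,
                         file.path(out_dir, "epu_assignments.tsv"),
                         sep = "\t", quote = FALSE)
    }

    stage <- "occupancy"
    promoters <- promoter_regions(
      genes[genes$source == "refseq_like", , drop = FALSE],
      params$promoter_half_width, layout)
    coloc <- list(); ann_sites <- list()
    for (cond in c("unstim", "stim")) {
      sites <- read_intervals(files[[paste0("sites_", cond)]], "bed6",
                              mark = "factor", condition = cond,
                              layout = layout)
      ann <- classify_binding_sites(sites, calls, promoters)
      ann_sites[[cond]] <- ann
      coloc[[cond]] <- colocalization_fractions(ann)
      topn <- top_n_sites(ann, min(params$top_n, nrow(ann)))
      coloc[[paste0(cond, "_top")]] <- colocalization_fractions(topn)
      data.table::fwrite(ann, file.path(
        out_dir, sprintf("site_annotations_%s.tsv", cond)),
        sep = "\t", quote = FALSE)
    }
    strat <- stratify_enhancers_by_binding(qualified,
                                           ann_sites$unstim)

    stage <- "promoter_dynamics"
    ip_u <- tags_to_rpm_track(read_tags(files$me2_unstim, layout),
                              layout, params)
    ip_s <- tags_to_rpm_track(read_tags(files$me2_stim, layout),
                              layout, params)
    in_u <- tags_to_rpm_track(read_tags(files$input_unstim, layout),
                              layout, params)
    in_s <- tags_to_rpm_track(read_tags(files$input_stim, layout),
                              layout, params)
    rec_u <- promoter_signal_ratio(ip_u, in_u, promoters,
                                   condition = "unstim")
    rec_s <- promoter_signal_ratio(ip_s, in_s, promoters,
                                   condition = "stim")
    genome_inducible <- promoters$gene %in% inducible_names
    post_pre <- rec_s$ratio / rec_u$ratio
    me2 <- data.frame(gene = promoters$gene,
                      inducible = genome_inducible,
                      ratio_unstim = rec_u$ratio,
                      ratio_stim = rec_s$ratio,
                      post_pre = post_pre, stringsAsFactors = FALSE)
    data.table::fwrite(me2, file.path(out_dir, "promoter_me2.tsv"),
                       sep = "\t", quote = FALSE)
    contrast <- if (sum(genome_inducible) >= 2 &&
                    sum(!genome_inducible) >= 2) {
      compare_promoter_sets(rec_s[genome_inducible, , drop = FALSE],
                            rec_s[!genome_inducible, , drop = FALSE])
    } else NULL

    stage <- "report"
    reason_counts <- function(x) {
      r <- unlist(strsplit(x[x != ""], ","))
      as.list(table(r))
    }
    summary <- list(
      enhancers = list(
        n_p300 = nrow(calls), n_qualified = nrow(qualified),
        n_intragenic = sum(qualified$location_class == "intragenic"),
        n_extragenic = nrow(extragenic),
        n_excluded_near_tes =
          sum(qualified$location_class == "excluded_near_tes"),
        rejection_reasons = reason_counts(calls$rejection_reasons),
        activity_classes = as.list(table(qualified$activity_class))),
      erna = list(
        n_loci = nrow(loci_u), n_passed = sum(loci_u$passed),
        exclusion_reasons = reason_counts(loci_u$exclusion_reasons),
        median_induction = induction$median_ratio),
      inducible = list(
        n_inducible_genes = sum(gene_calls$inducible),
        n_inducible_enhancers = sum(calls$inducible)),
      epu = if (!is.null(epu)) as.list(table(epu$reason)) else NULL,
      occupancy = list(
        colocalization = lapply(coloc, as.list),
        bound_fraction_overall = strat$fraction_overall,
        bound_fraction_by_class = as.list(strat$fraction_by_class)),
      promoter_me2 = list(
        mean_post_pre_inducible =
          if (any(genome_inducible))
            mean(post_pre[genome_inducible]) else NA,
        mean_post_pre_random = mean(post_pre[!genome_inducible]),
        inducible_vs_random_p =
          if (!is.null(contrast)) contrast$p_value else NA))
    summary
  }, error = on_fail)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
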