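# Enhancer-promoter units: chromosomes are partitioned into blocks at
# CTCF (insulator) site summits, and each extragenic enhancer is
# assigned to the nearest target-gene TSS within its block, up to a
# range cap. This is a documented simplification of published EPU
# construction: the assignment rule is isolated here so a richer
# variant can be swapped in.

#' Partition chromosomes into CTCF-delimited blocks
#'
#' Block boundaries are the CTCF peak summits; chromosome ends close
#' the terminal blocks. Duplicate summits collapse so no zero-length
#' block arises. An empty CTCF set yields one block per chromosome.
#'
#' @param ctcf_sites CTCF peak table (needs `chrom`, `summit`), may have
#'   zero rows.
#' @param layout [genome_layout()].
#' @return A `data.frame` of blocks: `chrom`, `start`, `end`,
#'   `block_id`. Blocks tile each chromosome without overlap.
#' @export
partition_by_ctcf <- function(ctcf_sites, layout) {
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    len <- layout$length[i]
    s <- ctcf_sites$summit[ctcf_sites$chrom == ch]
    s <- sort(unique(s[s > 0 & s < len]))
    b <- c(0, s, len)
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$block_id <- sprintf("block_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Index of the block containing each (chrom, pos) point.
block_of <- function(chrom, pos, blocks) {
  vapply(seq_along(chrom), function(i) {
    j <- which(blocks$chrom == chrom[i] & blocks$start <= pos[i] &
                 blocks$end > pos[i])
    if (!length(j)) NA_integer_ else j[1]
  }, integer(1))
}

#' Assign extragenic enhancers to genes within CTCF blocks
#'
#' Each enhancer is assigned to the nearest gene (summit-to-TSS
#' distance) whose TSS lies in the same CTCF block and within
#' `max_range`; ties break toward the lower TSS coordinate. Unassigned
#' enhancers carry a reason: `no_tss_in_block` when the block holds no
#' candidate TSS, `out_of_range` when all candidates exceed the cap.
#'
#' @param enhancers Enhancer call table (`enhancer_id`, `chrom`,
#'   `summit`).
#' @param genes Gene model table — typically a target subset such as
#'   the inducible genes.
#' @param blocks Output of [partition_by_ctcf()].
#' @param max_range Distance cap in bp (default 200000).
#' @return A `data.frame`: `enhancer_id`, `gene` (`NA` when
#'   unassigned), `distance`, `reason`
#'   (`assigned_nearest_in_block` / `no_tss_in_block` / `out_of_range`).
#' @export
assign_enhancers_to_genes <- function(enhancers, genes, blocks,
                                      max_range = 200000) {
  eb <- block_of(enhancers$chrom, enhancers$summit, blocks)
  if (anyNA(eb)) {
    stop("enhancer summit outside the partitioned layout: ",
         enhancers$enhancer_id[which(is.na(eb))[1]])
  }
  gb <- block_of(genes$chrom, genes$tss, blocks)
  out <- lapply(seq_len(nrow(enhancers)), function(i) {
    cand <- which(gb == eb[i])
    if (!length(cand)) {
      return(data.frame(enhancer_id = enhancers$enhancer_id[i],
                        gene = NA_character_, distance = NA_real_,
                        reason = "no_tss_in_block",
                        stringsAsFactors = FALSE))
    }
    d <- abs(genes$tss[cand] - enhancers$summit[i])
    in_range <- d <= max_range
    if (!any(in_range)) {
      return(data.frame(enhancer_id = enhancers$enhancer_id[i],
                        gene = NA_character_, distance = min(d),
                        reason = "out_of_range",
                        stringsAsFactors = FALSE))
    }
    cand <- cand[in_range]; d <- d[in_range]
    best <- cand[order(d, genes$tss[cand])][1]
    data.frame(enhancer_id = enhancers$enhancer_id[i],
               gene = genes$name[best],
               distance = abs(genes$tss[best] - enhancers$summit[i]),
               reason = "assigned_nearest_in_block",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
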