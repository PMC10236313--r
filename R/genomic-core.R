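# Coordinate convention: every in-memory table is 0-based, half-open
# [start, end), BED-style. 1-based formats are converted at the file
# boundary only. Interval distance is gap size in bp; half-open adjacency
# ([100,200) vs [200,300)) has distance 0 but does not overlap.

#' Genome layout
#'
#' A table of chromosome names and lengths defining the coordinate space
#' for every interval in the pipeline. All intervals must fall within
#' `[0, length)` of their chromosome.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @return A `data.frame` with columns `chrom` and `length`, of class
#'   `genome_layout`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) {
    stop("chrom and length differ in length")
  }
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("chromosome lengths must be positive")
  }
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.3f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chrom.sizes file needs two columns: ", path)
  genome_layout(dt[[1]], dt[[2]])
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  layout$length[i]
}

# Validate that intervals fall within the layout; `what` names the table
# in error messages.
check_bounds <- function(df, layout, what = "interval") {
  if (is.null(layout)) return(invisible(df))
  len <- chrom_length(layout, df$chrom)
  bad <- which(df$start < 0 | df$end > len)
  if (length(bad)) {
    stop(sprintf("%s outside genome layout at row %d (%s:%d-%d)",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]],
                 df$end[bad[1]]))
  }
  invisible(df)
}

# IRanges view of a 0-based half-open table (1-based closed internally).
as_iranges0 <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Read peak or interval files (BED3/BED6/narrowPeak dialects)
#'
#' Coordinates are kept 0-based half-open. Missing score columns default
#' to 0; the peak summit is taken from the narrowPeak summit-offset
#' column when present (and non-negative), else the interval midpoint.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`.
#'   `"auto"` picks by column count (3, 6, 10).
#' @param mark,condition Labels attached to every returned peak.
#' @param layout Optional [genome_layout()]; intervals are bounds-checked
#'   against it.
#' @return A `data.frame` of peaks: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit` (absolute bp), `mark`, `condition`.
#' @export
read_intervals <- function(path, format = c("auto", "bed3", "bed6",
                                            "narrowPeak"),
                           mark = NA_character_,
                           condition = NA_character_, layout = NULL) {
  format <- match.arg(format)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) {
    return(empty_peaks(mark, condition))
  }
  nc <- ncol(dt)
  if (format == "auto") {
    format <- if (nc >= 10) "narrowPeak" else if (nc >= 6) "bed6"
              else "bed3"
  }
  need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[format]]
  if (nc < need) {
    stop(sprintf("%s: %s needs %d columns, found %d", path, format,
                 need, nc))
  }
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("malformed interval in %s at line %d", path, bad[1]))
  }
  name <- if (nc >= 4) as.character(dt[[4]]) else
    sprintf("feature_%d", seq_along(chrom))
  score <- if (nc >= 5) suppressWarnings(as.numeric(dt[[5]])) else 0
  score[is.na(score)] <- 0
  strand <- if (nc >= 6) as.character(dt[[6]]) else "."
  summit <- floor((start + end) / 2)
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.numeric(dt[[10]]))
    use <- !is.na(off) & off >= 0
    summit[use] <- start[use] + off[use]
    bad_sum <- which(use & (summit < start | summit >= end))
    if (length(bad_sum)) {
      stop(sprintf("summit offset outside peak in %s at line %d", path,
                   bad_sum[1]))
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, strand = strand, summit = summit,
                    mark = mark, condition = condition,
                    stringsAsFactors = FALSE)
  check_bounds(out, layout, what = basename(path))
  out
}

empty_peaks <- function(mark = NA_character_, condition = NA_character_) {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             summit = numeric(), mark = character(),
             condition = character(), stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df A data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` are filled with defaults when absent.
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  n <- nrow(df)
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(df)) df$name else
      sprintf("feature_%d", seq_len(n)),
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a gene table (simplified refFlat-style)
#'
#' Expects a headerless TSV with columns: name, chrom, strand, txStart,
#' txEnd (0-based half-open transcription unit). Exon structure is not
#' modelled; a gene is its transcription unit.
#'
#' @param path File path.
#' @param source Annotation class, `"refseq_like"` or `"est_like"`.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @return A `data.frame` with `name`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`, `source`. The TSS is `start` on `+` and `end - 1` on
#'   `-`; the TES is the opposite terminus.
#' @export
read_gene_table <- function(path, source = c("refseq_like", "est_like"),
                            layout = NULL) {
  source <- match.arg(source)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 2, 3)))
  if (ncol(dt) < 5) stop("gene table needs 5 columns: ", path)
  gene_models(name = dt[[1]], chrom = dt[[2]], strand = dt[[3]],
              start = dt[[4]], end = dt[[5]], source = source,
              layout = layout)
}

#' Construct gene models from vectors
#'
#' @inheritParams read_gene_table
#' @param name,chrom,strand,start,end Parallel vectors describing
#'   transcription units (0-based half-open).
#' @return See [read_gene_table()].
#' @export
gene_models <- function(name, chrom, strand, start, end,
                        source = "refseq_like", layout = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0 | start >= end)) stop("invalid transcription unit")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be + or -")
  tss <- ifelse(strand == "+", start, end - 1)
  tes <- ifelse(strand == "+", end - 1, start)
  out <- data.frame(name = as.character(name),
                    chrom = as.character(chrom), start = start,
                    end = end, strand = as.character(strand), tss = tss,
                    tes = tes, source = source, stringsAsFactors = FALSE)
  check_bounds(out, layout, what = "gene")
  out
}

#' Write a gene table in the dialect read_gene_table() reads
#' @param genes Gene model table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(genes$name, genes$chrom, genes$strand,
                    format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read aligned tags (tagAlign-style BED)
#'
#' Accepts 4-column (chrom, start, end, strand) or 6-column BED with the
#' strand in column 6.
#'
#' @param path File path.
#' @param layout Optional [genome_layout()] for bounds checking.
#' @return A `data.frame` with `chrom`, `start`, `end`, `strand`.
#' @export
read_tags <- function(path, layout = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  strand_col <- if (ncol(dt) >= 6) 6L else 4L
  if (ncol(dt) < strand_col) stop("tag file needs a strand column: ", path)
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.numeric(dt[[2]]),
                    end = as.numeric(dt[[3]]),
                    strand = as.character(dt[[strand_col]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start < 0 | out$start >= out$end |
                 !(out$strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("malformed tag in %s at line %d", path, bad[1]))
  }
  check_bounds(out, layout, what = basename(path))
  out
}

#' Write tags as tagAlign (6-column BED)
#' @param tags Tag table (`chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @export
write_tags <- function(tags, path) {
  out <- data.frame(tags$chrom,
                    format(tags$start, scientific = FALSE, trim = TRUE),
                    format(tags$end, scientific = FALSE, trim = TRUE),
                    "N", 0, tags$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Promoter windows around gene TSSs
#'
#' @param genes Gene model table.
#' @param half_width Half-width of the window in bp (default 1000, i.e.
#'   TSS +/- 1 kb).
#' @param layout Optional [genome_layout()]; windows are clamped to
#'   chromosome bounds.
#' @return A `data.frame` with `gene`, `chrom`, `start`, `end`, `tss`.
#' @export
promoter_regions <- function(genes, half_width = 1000, layout = NULL) {
  start <- pmax(0, genes$tss - half_width)
  end <- genes$tss + half_width
  if (!is.null(layout)) end <- pmin(end, chrom_length(layout, genes$chrom))
  data.frame(gene = genes$name, chrom = genes$chrom, start = start,
             end = end, tss = genes$tss, stringsAsFactors = FALSE)
}

#' Distance from query intervals to the nearest gene TSS
#'
#' Distance is 0 when the TSS point lies inside the half-open query
#' interval (or is adjacent to it), the bp gap otherwise, and `Inf` when
#' no gene of the requested source class shares the chromosome.
#'
#' @param query A data.frame of intervals (`chrom`, `start`, `end`).
#' @param genes Gene model table.
#' @param source `"any"`, `"refseq_like"` or `"est_like"`.
#' @return Numeric vector of distances, one per query row.
#' @export
nearest_tss_distance <- function(query, genes,
                                 source = c("any", "refseq_like",
                                            "est_like")) {
  source <- match.arg(source)
  if (source != "any") genes <- genes[genes$source == source, ,
                                      drop = FALSE]
  if (nrow(genes) == 0) stop("no gene annotation for source ", source)
  point_distance(query, genes$chrom, genes$tss)
}

# Minimum distance from each query interval to a set of points; Inf when
# no point shares the query's chromosome.
point_distance <- function(query, point_chrom, point_pos) {
  vapply(seq_len(nrow(query)), function(i) {
    p <- point_pos[point_chrom == query$chrom[i]]
    if (!length(p)) return(Inf)
    d <- ifelse(p < query$start[i], query$start[i] - p,
                ifelse(p >= query$end[i], p - query$end[i], 0))
    min(pmax(d, 0))
  }, numeric(1))
}

#' Does each query interval overlap any feature?
#'
#' Overlap is >= 1 shared bp under half-open semantics; adjacent
#' intervals do not overlap.
#'
#' @param query Interval data.frame (`chrom`, `start`, `end`).
#' @param features Interval data.frame; may be empty.
#' @return Logical vector, one per query row.
#' @export
overlaps_any <- function(query, features) {
  if (is.null(features) || nrow(features) == 0) {
    return(rep(FALSE, nrow(query)))
  }
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    hits <- IRanges::countOverlaps(
      as_iranges0(query[qi, , drop = FALSE]),
      as_iranges0(features[fi, , drop = FALSE]))
    out[qi] <- hits > 0
  }
  out
}

#' Is each query interval fully contained in some feature?
#' @inheritParams overlaps_any
#' @return Logical vector, one per query row.
#' @export
contained_in_any <- function(query, features) {
  if (is.null(features) || nrow(features) == 0) {
    return(rep(FALSE, nrow(query)))
  }
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    hits <- IRanges::countOverlaps(
      as_iranges0(query[qi, , drop = FALSE]),
      as_iranges0(features[fi, , drop = FALSE]), type = "within")
    out[qi] <- hits > 0
  }
  out
}
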