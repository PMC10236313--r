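# Tag-level signal processing. The canonical order in the pipeline is
# deduplicate -> extend -> bin -> RPM; extension changes the dedup key,
# so the two do not commute and the order is fixed upstream.

#' Library statistics
#'
#' @param total_mapped Total mapped tag count (>= 1); the RPM/FPKM
#'   normalizer.
#' @param duplication_rate Fraction of tags removed as duplicates.
#' @return A list of class `library_stats`.
#' @export
library_stats <- function(total_mapped, duplication_rate = 0) {
  if (!is.finite(total_mapped) || total_mapped < 1) {
    stop("total_mapped must be >= 1")
  }
  structure(list(total_mapped = as.numeric(total_mapped),
                 duplication_rate = duplication_rate),
            class = "library_stats")
}

#' Extend tags past their 3' end
#'
#' Lengthens each tag by `extension` bp beyond its 3' end (the `end`
#' coordinate on `+`, the `start` coordinate on `-`), to approximate
#' sonicated fragment size. Results are clamped to chromosome bounds.
#' With `fixed_length = TRUE` the tag is instead resized to exactly
#' `extension` bp from its 5' end.
#'
#' @param tags Tag table (`chrom`, `start`, `end`, `strand`).
#' @param extension Extension in bp (default 100).
#' @param layout [genome_layout()] used for clamping.
#' @param fixed_length Resize to a fixed fragment length instead of
#'   extending.
#' @return Tag table with adjusted coordinates, input order preserved.
#' @export
extend_tags <- function(tags, extension = 100, layout,
                        fixed_length = FALSE) {
  if (extension < 0) stop("extension must be >= 0")
  check_bounds(tags, layout, what = "tag")
  len <- chrom_length(layout, tags$chrom)
  plus <- tags$strand == "+"
  start <- tags$start
  end <- tags$end
  if (fixed_length) {
    if (extension < 1) stop("fixed fragment length must be >= 1")
    end[plus] <- start[plus] + extension
    start[!plus] <- end[!plus] - extension
  } else {
    end[plus] <- end[plus] + extension
    start[!plus] <- start[!plus] - extension
  }
  tags$start <- pmax(0, start)
  tags$end <- pmin(end, len)
  tags
}

#' Remove duplicate tags
#'
#' Keeps one tag per (chrom, start, strand) key — the usual alignment
#' duplicate signature — and reports the removed fraction.
#'
#' @param tags Tag table.
#' @return A list: `tags` (deduplicated, first occurrence kept) and
#'   `duplication_rate` (removed / total; 0 for empty input).
#' @export
deduplicate_tags <- function(tags) {
  n <- nrow(tags)
  if (n == 0) return(list(tags = tags, duplication_rate = 0))
  key <- paste(tags$chrom, tags$start, tags$strand, sep = "\r")
  keep <- !duplicated(key)
  list(tags = tags[keep, , drop = FALSE],
       duplication_rate = (n - sum(keep)) / n)
}

#' Bin tag counts into a genome-wide coverage track
#'
#' Under `counting = "midpoint"` each tag increments the single bin
#' containing its midpoint, so the track total equals the tag count.
#' Under `"overlap"` a tag increments every bin it intersects.
#'
#' @param tags Tag table (typically extended).
#' @param layout [genome_layout()].
#' @param bin_size Bin width in bp (default 100).
#' @param counting `"midpoint"` or `"overlap"`.
#' @param strand Restrict to one strand (`"+"`/`"-"`) or use `"both"`.
#' @return A `coverage_track`: list with `bins` (named list of numeric
#'   vectors, one per chromosome), `bin_size`, `strand`, `units`
#'   (`"count"`), and the layout.
#' @export
bin_counts <- function(tags, layout, bin_size = 100,
                       counting = c("midpoint", "overlap"),
                       strand = "both") {
  counting <- match.arg(counting)
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (strand != "both") tags <- tags[tags$strand == strand, , drop = FALSE]
  check_bounds(tags, layout, what = "tag")
  bins <- lapply(seq_len(nrow(layout)), function(i) {
    nb <- ceiling(layout$length[i] / bin_size)
    ti <- tags[tags$chrom == layout$chrom[i], , drop = FALSE]
    if (nrow(ti) == 0) return(numeric(nb))
    if (counting == "midpoint") {
      idx <- floor(floor((ti$start + ti$end) / 2) / bin_size) + 1L
      as.numeric(tabulate(idx, nbins = nb))
    } else {
      first <- floor(ti$start / bin_size) + 1L
      last <- floor((ti$end - 1) / bin_size) + 1L
      last <- pmin(last, nb)
      v <- numeric(nb + 1L)
      # difference-array accumulation of interval cover counts
      for (j in seq_along(first)) {
        v[first[j]] <- v[first[j]] + 1
        v[last[j] + 1L] <- v[last[j] + 1L] - 1
      }
      cumsum(v)[seq_len(nb)]
    }
  })
  names(bins) <- layout$chrom
  structure(list(bins = bins, bin_size = bin_size, strand = strand,
                 units = "count", layout = layout),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track (%s): %d chromosome(s), bin %d bp, strand %s, total %.4g\n",
    x$units, length(x$bins), x$bin_size, x$strand,
    sum(vapply(x$bins, sum, numeric(1)))))
  invisible(x)
}

#' Normalize a raw coverage track to reads per million mapped
#'
#' @param track A raw-count `coverage_track`.
#' @param stats [library_stats()] providing the mapped-read total.
#' @return A `coverage_track` with `units = "rpm"`; every bin value is
#'   raw count x 1e6 / total_mapped.
#' @export
rpm_normalize <- function(track, stats) {
  if (stats$total_mapped < 1) stop("total_mapped must be >= 1")
  track$bins <- lapply(track$bins, function(v) v * 1e6 / stats$total_mapped)
  track$units <- "rpm"
  track
}

#' Aggregate (metagene) profile around anchor points
#'
#' For each anchor the `2 * half_width / bin_size` bins centred on the
#' bin containing the anchor are collected, reversed for `-`-strand
#' anchors, and averaged position-wise. Bins beyond a chromosome end
#' contribute nothing at their positions (position-wise mean over the
#' anchors that cover them).
#'
#' @param track A `coverage_track` (usually RPM).
#' @param anchors A data.frame with `chrom`, `pos` (bp) and optionally
#'   `strand` (defaults to `+`).
#' @param half_width Window half-width in bp; must be a multiple of the
#'   track bin size.
#' @return A list of class `anchor_profile` with `offset` (bp of bin
#'   starts relative to anchor), `mean` (position-wise means),
#'   `n_anchors`, `half_width`, `bin_size`.
#' @export
anchor_profile <- function(track, anchors, half_width = 5000) {
  if (nrow(anchors) == 0) stop("at least one anchor is required")
  bs <- track$bin_size
  if (half_width %% bs != 0) {
    stop("half_width must be a multiple of the bin size")
  }
  k <- half_width / bs
  nb <- 2L * k
  strand <- if ("strand" %in% names(anchors)) anchors$strand else
    rep("+", nrow(anchors))
  acc <- numeric(nb)
  cov <- numeric(nb)
  for (i in seq_len(nrow(anchors))) {
    v <- track$bins[[anchors$chrom[i]]]
    if (is.null(v)) stop("anchor chromosome not in track: ",
                         anchors$chrom[i])
    centre <- floor(anchors$pos[i] / bs)          # 0-based bin index
    idx <- (centre - k):(centre + k - 1L) + 1L    # 1-based
    ok <- idx >= 1L & idx <= length(v)
    vals <- rep(NA_real_, nb)
    vals[ok] <- v[idx[ok]]
    if (strand[i] == "-") vals <- rev(vals)
    use <- !is.na(vals)
    acc[use] <- acc[use] + vals[use]
    cov[use] <- cov[use] + 1
  }
  structure(list(offset = seq(-half_width, half_width - bs, by = bs),
                 mean = ifelse(cov > 0, acc / cov, NA_real_),
                 n_anchors = nrow(anchors), half_width = half_width,
                 bin_size = bs),
            class = "anchor_profile")
}

#' Fragments per kilobase per million mapped reads
#'
#' FPKM with an additive pseudocount of 0.01 — the FPKM-scale
#' equivalent of 1 read per 100 million mapped reads per kilobase — so
#' that empty regions have a defined, nonzero value.
#'
#' @param count Tag count in the region.
#' @param region_length Region length in bp (>= 1).
#' @param stats [library_stats()].
#' @param pseudocount FPKM-scale pseudocount (default 0.01).
#' @return FPKM value(s); vectorized over `count` / `region_length`.
#' @export
region_fpkm <- function(count, region_length, stats, pseudocount = 0.01) {
  if (any(region_length < 1)) stop("region_length must be >= 1")
  if (stats$total_mapped < 1) stop("total_mapped must be >= 1")
  count * 1e9 / (region_length * stats$total_mapped) + pseudocount
}

#' Count tags in a window
#'
#' @param tags Tag table.
#' @param chrom,start,end Window (0-based half-open).
#' @param method Assignment rule: `"five_prime"` counts a tag when its
#'   5' position (start on `+`, end-1 on `-`) lies in the window;
#'   `"midpoint"` uses the midpoint; `"overlap"` any shared bp.
#' @return Integer count.
#' @export
count_tags_in_window <- function(tags, chrom, start, end,
                                 method = c("five_prime", "midpoint",
                                            "overlap")) {
  method <- match.arg(method)
  t <- tags[tags$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0) return(0L)
  pos <- switch(method,
    five_prime = ifelse(t$strand == "+", t$start, t$end - 1),
    midpoint = floor((t$start + t$end) / 2),
    overlap = NULL)
  if (method == "overlap") {
    sum(t$start < end & t$end > start)
  } else {
    sum(pos >= start & pos < end)
  }
}

#' Mean track value over a window
#'
#' Mean of the bin values of the bins intersecting `[start, end)`.
#'
#' @param track A `coverage_track`.
#' @param chrom,start,end Window (0-based half-open).
#' @return Numeric mean; 0 for an empty bin range.
#' @export
window_mean <- function(track, chrom, start, end) {
  v <- track$bins[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  first <- floor(start / track$bin_size) + 1L
  last <- min(floor((end - 1) / track$bin_size) + 1L, length(v))
  if (first > last) return(0)
  mean(v[first:last])
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$bins), function(ch) {
    v <- track$bins[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.frame(chrom = ch, start = (nz - 1) * track$bin_size,
               end = pmin(nz * track$bin_size,
                          chrom_length(track$layout, ch)),
               value = v[nz], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
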