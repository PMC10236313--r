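layout1 <- genome_layout("chr1", 1e6)

test_that("tag extension grows past the 3' end and clamps", {
  t1 <- make_tags("chr1", 1000, 1036, "+")
  e1 <- extend_tags(t1, 100, layout1)
  expect_equal(c(e1$start, e1$end), c(1000, 1136))
  t2 <- make_tags("chr1", 1000, 1036, "-")
  e2 <- extend_tags(t2, 100, layout1)
  expect_equal(c(e2$start, e2$end), c(900, 1036))
  t3 <- make_tags("chr1", 30, 66, "-")
  e3 <- extend_tags(t3, 100, layout1)
  expect_equal(c(e3$start, e3$end), c(0, 66))
  # clamp at the chromosome end too
  t4 <- make_tags("chr1", 1e6 - 36, 1e6, "+")
  expect_equal(extend_tags(t4, 100, layout1)$end, 1e6)
  # fixed-fragment mode resizes from the 5' end
  e5 <- extend_tags(t1, 200, layout1, fixed_length = TRUE)
  expect_equal(c(e5$start, e5$end), c(1000, 1200))
  e6 <- extend_tags(t2, 200, layout1, fixed_length = TRUE)
  expect_equal(c(e6$start, e6$end), c(836, 1036))
})

test_that("deduplication keys on (chrom, start, strand)", {
  t <- make_tags("chr1", c(100, 100, 100), c(136, 136, 136),
                 c("+", "+", "+"))
  d <- deduplicate_tags(t)
  expect_equal(nrow(d$tags), 1)
  expect_equal(d$duplication_rate, 2 / 3)
  t2 <- make_tags("chr1", c(100, 100), c(136, 136), c("+", "-"))
  d2 <- deduplicate_tags(t2)
  expect_equal(nrow(d2$tags), 2)
  expect_equal(d2$duplication_rate, 0)
  d3 <- deduplicate_tags(t[0, ])
  expect_equal(nrow(d3$tags), 0)
  expect_equal(d3$duplication_rate, 0)
})

test_that("binning counts midpoints once and overlaps per bin", {
  t <- make_tags("chr1", 1000, 1136, "+")
  tr <- bin_counts(t, layout1, 100, "midpoint")
  expect_equal(tr$bins$chr1[11], 1)   # midpoint 1068 -> bin index 10
  expect_equal(sum(tr$bins$chr1), 1)
  tr2 <- bin_counts(t, layout1, 100, "overlap")
  expect_equal(tr2$bins$chr1[11:12], c(1, 1))
  expect_equal(sum(bin_counts(t[0, ], layout1)$bins$chr1), 0)
})

test_that("midpoint counting conserves the tag total", {
  set.seed(11)
  layout <- tiny_layout(len = 5e4, n = 2)
  iv <- random_intervals(500, layout, max_width = 300)
  tags <- make_tags(iv$chrom, iv$start, iv$end,
                    sample(c("+", "-"), 500, TRUE))
  ext <- extend_tags(tags, 100, layout)
  tr <- bin_counts(ext, layout, 100, "midpoint")
  expect_equal(sum(vapply(tr$bins, sum, numeric(1))), 500)
})

test_that("RPM normalization is exact and linear", {
  t <- make_tags("chr1", rep(1000, 5), rep(1100, 5), rep("+", 5))
  tr <- bin_counts(t, layout1, 100)
  expect_equal(rpm_normalize(tr, library_stats(1e6))$bins$chr1[11], 5)
  expect_equal(rpm_normalize(tr, library_stats(1e7))$bins$chr1[11], 0.5)
  tr2 <- tr
  tr2$bins$chr1 <- tr$bins$chr1 * 4
  expect_equal(rpm_normalize(tr2, library_stats(1e6))$bins$chr1,
               4 * rpm_normalize(tr, library_stats(1e6))$bins$chr1)
  expect_error(library_stats(0), ">= 1")
})

test_that("anchor profiles average, reverse and truncate correctly", {
  tr <- bin_counts(make_tags("chr1", 1, 2, "+"), layout1, 100)
  tr$bins$chr1 <- rep(2.5, length(tr$bins$chr1))
  pr <- anchor_profile(tr, data.frame(chrom = "chr1", pos = 500000),
                       half_width = 5000)
  expect_length(pr$mean, 100)
  expect_true(all(pr$mean == 2.5))
  # asymmetric track: minus-strand anchor reverses the window
  tr$bins$chr1 <- seq_along(tr$bins$chr1)
  plus <- anchor_profile(tr, data.frame(chrom = "chr1", pos = 500000,
                                        strand = "+"), 5000)
  minus <- anchor_profile(tr, data.frame(chrom = "chr1", pos = 500000,
                                         strand = "-"), 5000)
  expect_equal(minus$mean, rev(plus$mean))
  # n identical anchors equal the single-anchor profile
  three <- anchor_profile(tr, data.frame(chrom = "chr1",
                                         pos = rep(500000, 3)), 5000)
  expect_equal(three$mean, plus$mean)
  # anchor near the chromosome start: out-of-range bins uncovered
  near <- anchor_profile(tr, data.frame(chrom = "chr1", pos = 200),
                         half_width = 5000)
  expect_true(all(is.na(near$mean[1:48])))
  expect_false(anyNA(near$mean[49:100]))
  expect_error(anchor_profile(tr, data.frame(chrom = "chr1",
                                             pos = 1)[0, ], 5000),
               "anchor")
  expect_error(anchor_profile(tr, data.frame(chrom = "chr1", pos = 1),
                              half_width = 5050), "multiple")
})

test_that("FPKM applies the 0.01 pseudocount exactly", {
  expect_identical(region_fpkm(0, 1000, library_stats(1e8)), 0.01)
  expect_equal(region_fpkm(200, 2000, library_stats(5e7)), 2.01)
  expect_identical(region_fpkm(0, 500, library_stats(2e8)), 0.01)
  counts <- 0:50
  f <- region_fpkm(counts, 1000, library_stats(1e6))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0.01))
})

test_that("window tag counting honours the assignment rule", {
  tags <- make_tags("chr1", c(95, 100, 150), c(131, 136, 186),
                    c("+", "+", "-"))
  # five_prime: + uses start (95 outside, 100 in), - uses end-1
  # (= 185, outside)
  expect_equal(count_tags_in_window(tags, "chr1", 100, 180,
                                    "five_prime"), 1)
  expect_equal(count_tags_in_window(tags, "chr1", 100, 180,
                                    "midpoint"), 3)
  expect_equal(count_tags_in_window(tags, "chr1", 130, 140,
                                    "overlap"), 2)
})

test_that("bedGraph output reflects nonzero bins", {
  t <- make_tags("chr1", c(1000, 1200), c(1100, 1300), c("+", "+"))
  tr <- bin_counts(t, layout1, 100)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  bg <- read.table(path, sep = "\t")
  expect_equal(nrow(bg), 2)
  expect_equal(bg$V2, c(1000, 1200))
})
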