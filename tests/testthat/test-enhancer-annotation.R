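# Shared toy annotation: one RefSeq gene and one EST entry per
# chromosome arm, far enough apart that each predicate can be toggled
# independently.
toy_genes <- gene_models(c("g1", "g2"), c("chr1", "chr1"),
                         c("+", "+"), c(100000, 300000),
                         c(120000, 320000))
toy_ests <- gene_models("e1", "chr1", "+", 500000, 520000,
                        source = "est_like")
toy_ann <- rbind(toy_genes, toy_ests)

test_that("each qualification predicate toggles independently", {
  me1 <- make_intervals("chr1", 199000, 201000)
  me3 <- make_intervals("chr1", 99500, 100500)
  ok <- make_peaks("chr1", 199500, 200500, score = 75)
  calls <- qualify_enhancers(ok, me3, me1, toy_ann)
  expect_true(calls$qualified)
  expect_equal(calls$rejection_reasons, "")

  low <- make_peaks("chr1", 199500, 200500, score = 55)
  expect_equal(qualify_enhancers(low, me3, me1,
                                 toy_ann)$rejection_reasons,
               "low_score")
  # exactly at the gate qualifies (score >= 60)
  expect_true(qualify_enhancers(make_peaks("chr1", 199500, 200500,
                                           score = 60),
                                me3, me1, toy_ann)$qualified)

  # 800 bp from the RefSeq TSS at 100000
  near <- make_peaks("chr1", 97400, 99200, score = 75)
  me1b <- make_intervals("chr1", 97000, 99500)
  expect_equal(qualify_enhancers(near, me3, me1b,
                                 toy_ann)$rejection_reasons,
               "refseq_tss_proximity")

  # 1.5 kb from the EST TSS at 500000 trips only the EST radius
  est_near <- make_peaks("chr1", 497500, 498500, score = 75)
  me1c <- make_intervals("chr1", 497000, 499000)
  expect_equal(qualify_enhancers(est_near, me3, me1c,
                                 toy_ann)$rejection_reasons,
               "est_tss_proximity")

  # H3K4me3 overlap and missing H3K4me1 both recorded (no
  # short-circuit)
  clash <- make_peaks("chr1", 99900, 100900, score = 75)
  r <- qualify_enhancers(clash, me3, make_intervals("chr2", 1, 2),
                         toy_ann)$rejection_reasons
  expect_true(grepl("h3k4me3_overlap", r))
  expect_true(grepl("no_h3k4me1", r))
  expect_true(grepl("refseq_tss_proximity", r))

  # chromosome with no annotation cannot be certified
  orphan <- make_peaks("chr9", 199500, 200500, score = 75)
  expect_equal(qualify_enhancers(orphan, me3,
                                 make_intervals("chr9", 199000, 201000),
                                 toy_ann)$rejection_reasons,
               "unassignable")
  expect_error(qualify_enhancers(ok, me3, NULL, toy_ann), "H3K4me1")
})

test_that("qualification matches a brute-force predicate oracle", {
  set.seed(101)
  layout <- tiny_layout(len = 2e6, n = 2)
  iv <- random_intervals(80, layout, max_width = 20000)
  genes <- gene_models(sprintf("g%02d", 1:80), iv$chrom,
                       sample(c("+", "-"), 80, TRUE), iv$start, iv$end,
                       source = sample(c("refseq_like", "est_like"),
                                       80, TRUE, prob = c(.7, .3)))
  me3 <- random_intervals(120, layout, max_width = 3000)
  me1 <- random_intervals(400, layout, max_width = 4000)
  iv <- random_intervals(1000, layout, max_width = 1500)
  p300 <- make_peaks(iv$chrom, iv$start, iv$end,
                     score = round(runif(1000, 40, 120), 1))
  cfg <- enhancer_rule_config()
  calls <- qualify_enhancers(p300, me3, me1, genes, cfg)
  oracle <- brute_qualify(p300, me3, me1, genes, cfg)
  expect_equal(sorted_reasons(calls$rejection_reasons), oracle)
  expect_equal(calls$qualified, oracle == "")
})

test_that("raising the score gate only shrinks the qualified set", {
  set.seed(102)
  layout <- tiny_layout(len = 2e6)
  iv <- random_intervals(50, layout, max_width = 15000)
  genes <- gene_models(sprintf("g%02d", 1:50), iv$chrom, "+",
                       iv$start, iv$end)
  me1 <- random_intervals(300, layout, max_width = 5000)
  iv <- random_intervals(400, layout, max_width = 1500)
  p300 <- make_peaks(iv$chrom, iv$start, iv$end,
                     score = round(runif(400, 40, 120), 1))
  prev <- NULL
  for (gate in c(40, 60, 80, 100)) {
    cfg <- enhancer_rule_config(min_score = gate)
    q <- qualify_enhancers(p300, p300[0, ], me1, genes, cfg)
    ids <- q$enhancer_id[q$qualified]
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("location classes are exclusive and exhaustive", {
  me1 <- make_intervals("chr1", c(104000, 124500, 199000),
                        c(106000, 126500, 201000))
  p <- make_peaks("chr1", c(104500, 124800, 199500),
                  c(105500, 125800, 200500), score = 80)
  calls <- qualify_enhancers(p, p[0, ], me1, toy_ann)
  calls <- split_location_class(calls, toy_ann)
  # inside g1; 4.8-5.8 kb past g1 TES (119999) -> within 5 kb? gap is
  # 124800-120000 = 4800 < 5000 -> excluded_near_tes; far peak
  # extragenic
  expect_equal(calls$location_class,
               c("intragenic", "excluded_near_tes", "extragenic"))
  cls <- calls$location_class[calls$qualified]
  expect_true(all(cls %in% c("intragenic", "extragenic",
                             "excluded_near_tes")))
})

test_that("activity classes cover both marks, neither and both", {
  p <- make_peaks("chr1", c(1000, 2000, 3000, 4000) * 100,
                  c(1000, 2000, 3000, 4000) * 100 + 500, score = 80)
  me1 <- make_intervals("chr1", p$start - 500, p$end + 500)
  genes <- gene_models("far", "chr1", "+", 900000, 950000)
  calls <- qualify_enhancers(p, p[0, ], me1, genes)
  ac <- make_intervals("chr1", c(100000, 400000), c(100500, 400500))
  me <- make_intervals("chr1", c(300000, 400000), c(300500, 400500))
  calls <- assign_activity_class(calls, ac, me)
  expect_equal(calls$activity_class,
               c("active", "intermediate", "poised", "conflicted"))
})
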