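occ_fixture <- function() {
  layout <- genome_layout("chr1", 1e6)
  genes <- gene_models("g1", "chr1", "+", 100000, 120000)
  promoters <- promoter_regions(genes, 1000, layout)
  me1 <- make_intervals("chr1", 499000, 501000)
  p300 <- make_peaks("chr1", 499500, 500500, score = 80)
  calls <- qualify_enhancers(p300, p300[0, ], me1, genes)
  list(layout = layout, genes = genes, promoters = promoters,
       calls = calls)
}

test_that("site categories take promoter precedence and rank by
           score", {
  fx <- occ_fixture()
  sites <- make_peaks("chr1", c(499800, 100200, 300000),
                      c(500200, 100600, 300400),
                      score = c(50, 90, 70))
  ann <- classify_binding_sites(sites, fx$calls, fx$promoters)
  expect_equal(ann$category, c("enhancer", "promoter", "other"))
  expect_equal(ann$rank_by_score, c(3, 1, 2))
  fr <- colocalization_fractions(ann)
  expect_equal(unname(fr), c(100, 100, 100) / 3)
  expect_equal(sum(fr), 100)
  expect_error(colocalization_fractions(ann[0, ]), "no annotated")
})

test_that("colocalization arithmetic matches a 70/10/20 composition", {
  ann <- data.frame(category = rep(c("enhancer", "promoter", "other"),
                                   c(7, 1, 2)))
  expect_equal(unname(colocalization_fractions(ann)), c(70, 10, 20))
})

test_that("top_n selection is deterministic under permutation and
           ties", {
  set.seed(71)
  sites <- make_peaks("chr1", seq(1000, by = 1000, length.out = 10),
                      seq(1400, by = 1000, length.out = 10),
                      score = c(9, 8, 7, 7, 6, 5, 4, 3, 2, 1))
  top <- top_n_sites(sites, 3)
  expect_equal(top$score, c(9, 8, 7))
  expect_equal(top$start[3], 3000)  # tie at 7 -> lower coordinate
  perm <- sites[sample(10), ]
  expect_equal(top_n_sites(perm, 3)$start, top$start)
  expect_warning(all10 <- top_n_sites(sites, 99), "available")
  expect_equal(nrow(all10), 10)
  expect_error(top_n_sites(sites, 0), ">= 1")
})

test_that("binding stratification guards empty classes", {
  fx <- occ_fixture()
  calls <- assign_activity_class(fx$calls,
                                 make_intervals("chr1", 499000, 501000),
                                 make_intervals("chr1", 1, 2))
  sites <- make_peaks("chr1", 499800, 500200, score = 50)
  out <- stratify_enhancers_by_binding(calls, sites)
  expect_equal(out$fraction_overall, 100)
  expect_equal(unname(out$fraction_by_class["active"]), 100)
  expect_true(is.na(out$fraction_by_class["poised"]))
  out2 <- stratify_enhancers_by_binding(calls, sites[0, ])
  expect_equal(out2$fraction_overall, 0)
})

test_that("promoter signal ratios use window means with symmetric
           epsilon", {
  layout <- genome_layout("chr1", 200000)
  mk_track <- function(v) {
    tr <- bin_counts(make_tags("chr1", 1, 37, "+")[0, ], layout, 100)
    tr$bins$chr1[] <- v
    tr$units <- "rpm"
    tr
  }
  genes <- gene_models("g1", "chr1", "+", 100000, 120000)
  prom <- promoter_regions(genes, 1000, layout)
  rec <- promoter_signal_ratio(mk_track(4), mk_track(2), prom)
  expect_equal(rec$ratio, 4.01 / 2.01)
  expect_equal(promoter_signal_ratio(mk_track(3), mk_track(3),
                                     prom)$ratio, 1)
  expect_equal(promoter_signal_ratio(mk_track(0), mk_track(0),
                                     prom)$ratio, 1)
})

test_that("promoter ratios are depth-invariant for RPM tracks", {
  set.seed(72)
  layout <- genome_layout("chr1", 1e5)
  genes <- gene_models(c("g1", "g2"), "chr1", "+", c(20000, 60000),
                       c(30000, 70000))
  prom <- promoter_regions(genes, 1000, layout)
  n <- 5000
  start <- floor(runif(n) * (1e5 - 36))
  tags <- make_tags("chr1", start, start + 36,
                    sample(c("+", "-"), n, TRUE))
  ip <- tags[1:2500, ]; input <- tags[2501:5000, ]
  r1 <- promoter_signal_ratio(
    rpm_normalize(bin_counts(ip, layout), library_stats(2500)),
    rpm_normalize(bin_counts(input, layout), library_stats(2500)),
    prom)
  # triplicate both libraries: RPM identical, ratios identical
  trip <- function(t) t[rep(seq_len(nrow(t)), 3), ]
  r3 <- promoter_signal_ratio(
    rpm_normalize(bin_counts(trip(ip), layout), library_stats(7500)),
    rpm_normalize(bin_counts(trip(input), layout),
                  library_stats(7500)),
    prom)
  expect_equal(r3$ratio, r1$ratio)
})

test_that("promoter-set comparison supports paired and unpaired
           contrasts", {
  set.seed(73)
  a <- data.frame(gene = sprintf("g%02d", 1:46),
                  ratio = rnorm(46, 2, 0.2))
  b <- data.frame(gene = sprintf("h%02d", 1:67),
                  ratio = rnorm(67, 1, 0.2))
  out <- compare_promoter_sets(a, b)
  expect_equal(out$n_a, 46)
  expect_equal(out$n_b, 67)
  expect_lt(out$p_value, 1e-6)
  expect_gt(out$difference, 0.5)
  same <- compare_promoter_sets(a, a, paired = TRUE)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_promoter_sets(a, b, paired = TRUE), "matched")
  expect_error(compare_promoter_sets(a[1, ], b), "at least 2")
})

test_that("planted 2-fold promoter depletion is recovered from
           simulated counts", {
  set.seed(74)
  layout <- genome_layout("chr1", 2e6)
  iv <- seq(50000, by = 100000, length.out = 15)
  genes <- gene_models(sprintf("g%02d", 1:15), "chr1", "+", iv,
                       iv + 10000)
  prom <- promoter_regions(genes, 1000, layout)
  sim_lib <- function(rate_mult) {
    tags <- do.call(rbind, lapply(seq_len(nrow(prom)), function(i) {
      n <- rpois(1, 800 * rate_mult)
      s <- floor(runif(n, prom$start[i], prom$end[i] - 36))
      make_tags("chr1", s, s + 36, sample(c("+", "-"), n, TRUE))
    }))
    # fixed nominal depth: the planted windows are a negligible share
    # of a real library, so depletion must not rescale the normalizer
    rpm_normalize(bin_counts(tags, layout), library_stats(1e6))
  }
  input <- sim_lib(1)
  pre <- promoter_signal_ratio(sim_lib(1), input, prom)
  post <- promoter_signal_ratio(sim_lib(0.5), input, prom)
  expect_lt(abs(mean(post$ratio / pre$ratio) - 0.5), 0.5 * 0.1)
})
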