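erna_enh <- function(summit, chrom = "chr1") {
  data.frame(enhancer_id = sprintf("e%03d", seq_along(summit)),
             chrom = chrom, summit = summit, stringsAsFactors = FALSE)
}

test_that("window membership and counts follow the summit anchors", {
  layout <- genome_layout("chr1", 1e6)
  tags <- make_tags("chr1", c(100500, 101200, 99064),
                    c(100536, 101236, 99100), c("+", "+", "-"))
  loci <- build_erna_loci(erna_enh(100000), tags, library_stats(1e6),
                          layout)
  # - tag 5' end is 99099, inside [98000, 100000)
  expect_equal(loci$plus_down, 2)
  expect_equal(loci$minus_up, 1)
  expect_equal(loci$plus_far, 0)
  expect_equal(loci$minus_far, 0)
  expect_equal(loci$fpkm_plus, 2 * 1e9 / (2000 * 1e6) + 0.01)
})

test_that("windows clamp at chromosome bounds and empty loci floor at
           the pseudocount", {
  layout <- genome_layout("chr1", 1e6)
  none <- make_tags("chr1", 1, 37, "+")[0, ]
  loci <- build_erna_loci(erna_enh(1000), none, library_stats(1e6),
                          layout)
  expect_equal(loci$len_minus_up, 1000)
  expect_equal(loci$len_minus_far, 0)
  expect_identical(loci$fpkm_plus, 0.01)
  expect_identical(loci$fpkm_minus, 0.01)
  expect_error(build_erna_loci(
    data.frame(enhancer_id = "x", chrom = "chr1", summit = NA),
    none, library_stats(1e6), layout), "summit")
})

filtered_locus <- function(pd, mu, pf = 0, mf = 0, fpkm = 0.5) {
  data.frame(enhancer_id = "e1", chrom = "chr1", summit = 500000,
             plus_down = pd, minus_up = mu, plus_far = pf,
             minus_far = mf, len_plus_down = 2000, len_minus_up = 2000,
             len_plus_far = 2000, len_minus_far = 2000,
             fpkm_plus = fpkm, fpkm_minus = fpkm, passed = NA,
             exclusion_reasons = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("exclusion filters fire on their documented conditions", {
  cfg <- erna_filter_config()
  # ratio (600+1)/(100+1) = 5.95 > 5
  r <- apply_erna_filters(filtered_locus(600, 100), cfg)
  expect_equal(r$exclusion_reasons, "strand_ratio")
  # exactly 5 is allowed ("more than 5")
  r2 <- apply_erna_filters(filtered_locus(499, 99), cfg)
  expect_true(r2$passed)
  # far window hotter than proximal
  r3 <- apply_erna_filters(filtered_locus(20, 20, pf = 30), cfg)
  expect_equal(r3$exclusion_reasons, "flanking_signal")
  # balanced and quiet passes
  r4 <- apply_erna_filters(filtered_locus(24, 20, pf = 5, mf = 5), cfg)
  expect_true(r4$passed)
  # repeat flag needs the FPKM gate too
  r5 <- apply_erna_filters(filtered_locus(24, 20, fpkm = 0.5), cfg,
                           repeat_flags = TRUE)
  expect_true(r5$passed)
  r6 <- apply_erna_filters(filtered_locus(24, 20, fpkm = 2), cfg,
                           repeat_flags = TRUE)
  expect_equal(r6$exclusion_reasons, "repeat_signal")
  # blacklist overlap anywhere in the 4-window span
  bl <- make_intervals("chr1", 503000, 503500)
  r7 <- apply_erna_filters(filtered_locus(24, 20), cfg, rrna_blacklist = bl)
  expect_equal(r7$exclusion_reasons, "rrna_homology")
  # symmetric option also catches minus-dominant loci
  r8 <- apply_erna_filters(filtered_locus(100, 600),
                           erna_filter_config(symmetric_ratio = TRUE))
  expect_equal(r8$exclusion_reasons, "strand_ratio")
  expect_true(apply_erna_filters(filtered_locus(100, 600), cfg)$passed)
})

test_that("filters are idempotent and match the brute-force oracle", {
  set.seed(55)
  cfg <- erna_filter_config()
  n <- 400
  loci <- do.call(rbind, lapply(seq_len(n), function(i) {
    filtered_locus(rpois(1, 40), rpois(1, 40), rpois(1, 30),
                   rpois(1, 30), fpkm = runif(1, 0, 3))
  }))
  loci$enhancer_id <- sprintf("e%03d", seq_len(n))
  loci$summit <- seq(100000, by = 20000, length.out = n)
  flags <- runif(n) < 0.3
  bl <- make_intervals("chr1", loci$summit[seq(1, n, by = 7)] + 3000,
                       loci$summit[seq(1, n, by = 7)] + 3400)
  once <- apply_erna_filters(loci, cfg, bl, flags)
  twice <- apply_erna_filters(once, cfg, bl, flags)
  expect_identical(once, twice)
  expect_equal(sorted_reasons(once$exclusion_reasons),
               brute_erna_reasons(loci, cfg, bl, flags))
  expect_equal(once$passed, once$exclusion_reasons == "")
})

test_that("induction ratios divide matched total FPKM", {
  u <- filtered_locus(10, 10); u$fpkm_plus <- 1; u$fpkm_minus <- 1.01
  s <- u; s$fpkm_plus <- 2; s$fpkm_minus <- 2.02
  out <- erna_induction(u, s)
  expect_equal(out$per_locus$ratio, 2.0)
  expect_equal(erna_induction(u, u)$per_locus$ratio, 1.0)
  # zero-count unstim locus: denominator floored at 0.02
  z <- u; z$fpkm_plus <- 0.01; z$fpkm_minus <- 0.01
  s2 <- u; s2$fpkm_plus <- 2.01; s2$fpkm_minus <- 0.01
  expect_equal(erna_induction(z, s2)$per_locus$ratio, 101)
  bad <- s; bad$enhancer_id <- "other"
  expect_error(erna_induction(u, bad), "unmatched")
})

test_that("quantified FPKM recovers planted symmetric rates", {
  # Poisson counts at rate lambda per proximal window: total FPKM must
  # sit within 3 SE of its expectation for nearly all loci
  set.seed(77)
  layout <- genome_layout("chr1", 1e8)
  lambda <- 40
  n <- 200
  summits <- seq(5e4, by = 5e5, length.out = n)
  tags <- do.call(rbind, lapply(summits, function(s) {
    np <- rpois(1, lambda); nm <- rpois(1, lambda)
    sp <- floor(runif(np, s, s + 2000 - 36))
    sm <- floor(runif(nm, s - 2000, s - 36))
    rbind(make_tags("chr1", sp, sp + 36, rep("+", np)),
          make_tags("chr1", sm, sm + 36, rep("-", nm)))
  }))
  stats <- library_stats(nrow(tags))
  loci <- build_erna_loci(erna_enh(summits), tags, stats, layout)
  scale <- 1e9 / (2000 * stats$total_mapped)
  expected <- 2 * lambda * scale + 0.02
  se <- sqrt(2 * lambda) * scale
  total <- loci$fpkm_plus + loci$fpkm_minus
  expect_gte(mean(abs(total - expected) <= 3 * se), 0.95)
})
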