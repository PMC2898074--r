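test_that("site_density arithmetic and guards", {
  expect_equal(site_density(0, 1000)$per_nt, 0)
  expect_equal(site_density(10, 100)$per_100nt, 10)
  d <- site_density(c(18704, 111192), c(358663, 1570606))
  expect_equal(round(d$per_100nt, 2), c(5.21, 7.08))
  expect_error(site_density(5, 0), "positive")
  expect_error(site_density(-1, 10), "non-negative")
})

test_that("summarize_densities uses type-7 quartiles and the totals-ratio mean", {
  rec <- function(n, L, cls = "pairing")
    data.frame(pair_id = paste0("p", seq_along(n)), region_class = cls,
               site_count = n, length_nt = L)
  # constant densities
  s <- summarize_densities(rec(rep(5L, 10), rep(100L, 10)))
  expect_equal(s$median, 0.05)
  expect_equal(c(s$q1, s$q3), c(0.05, 0.05))
  # quartiles equal a direct order-statistics computation
  s2 <- summarize_densities(rec(c(1L, 2L, 3L, 4L), rep(1L, 4)))
  expect_equal(c(s2$q1, s2$median, s2$q3), c(1.75, 2.5, 3.25))
  # aggregate mean is sum(n)/sum(L), not the mean of ratios
  s3 <- summarize_densities(rec(c(10L, 0L), c(100L, 900L)))
  expect_equal(s3$mean_per_100nt, 1.0)
  expect_equal(s3$median, 0.05)
  expect_error(summarize_densities(rec(1L, 10L), "nonpairing"), "no density")
})

test_that("wilcoxon_rank_sum matches full-enumeration oracle for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(70)
  for (n in 1:7) {
    for (rep in 1:3) {
      a <- rnorm(n); b <- rnorm(n, 0.8)
      wt <- wilcoxon_rank_sum(a, b)
      expect_true(wt$exact)
      expect_equal(wt$p, oracle_wilcoxon_p(a, b), tolerance = 1e-12,
                   label = sprintf("n=m=%d rep=%d", n, rep))
      expect_equal(wt$W, sum(rank(c(a, b))[seq_len(n)]))
    }
  }
  # identical multisets -> p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(2, 1))$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(3, 5), rep(3, 4))$p, 1)
})

test_that("exact and normal-approximation paths agree closely at n=m=10", {
  set.seed(71)
  for (r in 1:20) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    pe <- wilcoxon_rank_sum(a, b)$p  # exact path (n <= 10, no ties)
    pn <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE)$p.value)
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("scale equivariance: scaling counts and lengths together changes nothing", {
  set.seed(72)
  rec <- data.frame(pair_id = rep(paste0("p", 1:12), 2),
                    region_class = rep(c("pairing", "nonpairing"), each = 12),
                    site_count = rpois(24, 8),
                    length_nt = sample(100:500, 24, TRUE))
  r1 <- compare_regions(rec)
  rec2 <- rec
  rec2$site_count <- rec2$site_count * 7L
  rec2$length_nt <- rec2$length_nt * 7L
  r2 <- compare_regions(rec2)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
  expect_equal(r1$pairing$median, r2$pairing$median)
  expect_equal(r1$nonpairing$mean_per_100nt, r2$nonpairing$mean_per_100nt)
})

test_that("compare_regions assembles summaries, direction and degenerate cases", {
  rec <- data.frame(pair_id = c("p1", "p1"),
                    region_class = c("pairing", "nonpairing"),
                    site_count = c(1L, 9L), length_nt = c(100L, 100L))
  r <- compare_regions(rec)
  expect_equal(r$pairing$median, 0.01)
  expect_equal(r$nonpairing$median, 0.09)
  expect_equal(r$p_two_sided, 1)  # exact test with n = m = 1
  expect_equal(r$direction, "nonpairing > pairing")

  # a synthetic planted-depletion set gets the right direction
  cfg <- synthetic_config(n_pairs = 60, overlap_len_range = c(150, 300),
                          flank_len_range = c(150, 300),
                          rate_pairing = 0.01, rate_nonpairing = 0.03,
                          mirna_panel_size = 5, seed = 6)
  td <- truth_densities(suppressWarnings(generate_pair_set(cfg)))
  rs <- compare_regions(td)
  expect_equal(rs$direction, "nonpairing > pairing")
  expect_lt(rs$p_two_sided, 0.01)
})

test_that("density_records counts sites per pair and class with scanned lengths", {
  cfg <- synthetic_config(n_pairs = 3, overlap_len_range = c(100, 150),
                          flank_len_range = c(80, 120), rate_pairing = 0.01,
                          rate_nonpairing = 0.02, mirna_panel_size = 4,
                          seed = 19)
  ps <- generate_pair_set(cfg)
  parts <- partition_pairs(ps$records, ps$pairs)
  sites <- scan_regions(ps$mirnas, parts, scan_params())
  rec <- density_records(sites, parts)
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$density, rec$site_count / rec$length_nt)
  g <- ps$truth$geometry
  i <- match(rec$pair_id[rec$region_class == "pairing"], g$pair_id)
  expect_equal(rec$length_nt[rec$region_class == "pairing"],
               g$overlap_len[i])
  # under strands = "sense" the non-pairing length shrinks to the sense flanks
  rec_s <- density_records(sites[sites$transcript_id %in% g$sense_id, ],
                           parts, strands = "sense")
  expect_true(all(rec_s$length_nt[rec_s$region_class == "nonpairing"] <
                    rec$length_nt[rec$region_class == "nonpairing"]))
})
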