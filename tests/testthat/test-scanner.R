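test_that("a perfect 22-mer complement scores 215 under default params", {
  set.seed(5)
  mir <- list(id = "m", seq = rand_dna(22))
  target <- paste0(rand_dna(30), revcomp(mir$seq), rand_dna(25))
  h <- align_mirna(mir, target, scan_params())
  expect_gte(nrow(h), 1L)
  # 7 seed positions at 5*4 plus 15 at 5: 140 + 75 = 215
  expect_equal(h$score[1], 215)
  expect_equal(h$t_start[1], 30L)
  expect_equal(h$t_end[1], 52L)
  expect_equal(c(h$q_start[1], h$q_end[1]), c(1L, 22L))
})

test_that("align_mirna validates miRNA length", {
  expect_error(align_mirna(list(id = "m", seq = "ACGTAC"), "ACGTACGT"),
               "shorter than 7")
  expect_warning(align_mirna(list(id = "m", seq = "ACGTACGTAC"),
                             strrep("ACGT", 10),
                             scan_params(score_threshold = 500)),
                 "shorter than 16")
})

test_that("align_mirna matches the brute-force oracle on random instances", {
  p <- scan_params(score_threshold = 1)
  set.seed(101)
  for (r in 1:60) {
    n <- sample(20:60, 1)
    ml <- sample(c(16L, 20L, 22L), 1)
    tg <- rand_dna(n)
    mi <- rand_dna(ml)
    hits <- suppressWarnings(align_mirna(list(id = "m", seq = mi), tg, p))
    impl <- if (nrow(hits)) max(hits$score) else 0
    expect_equal(impl, oracle_local_score(tg, mi, p), tolerance = 1e-9)
  }
})

test_that("per-miRNA hits never overlap; different miRNAs may", {
  set.seed(33)
  mir <- list(id = "m", seq = rand_dna(22))
  target <- paste0(rand_dna(12), revcomp(mir$seq), rand_dna(9),
                   revcomp(mir$seq), rand_dna(12))
  h <- align_mirna(mir, target, scan_params())
  h <- h[order(h$t_start), ]
  expect_gte(nrow(h), 2L)
  expect_true(all(h$t_start[-1] >= h$t_end[-nrow(h)]))

  # two distinct miRNAs whose complements occupy the same locus: both are
  # reported (the non-overlap rule is per miRNA only)
  m1 <- list(id = "m1", seq = rand_dna(22))
  m2 <- list(id = "m2", seq = m1$seq)
  tg <- paste0(rand_dna(20), revcomp(m1$seq), rand_dna(20))
  part <- structure(list(pair_id = "p", sense_id = "s", antisense_id = "a",
                         pairing = data.frame(transcript_id = "s", start = 0L,
                                              end = nchar(tg), seq = tg),
                         nonpairing = NULL, overlap_len = nchar(tg),
                         score = 0, passes_filter = TRUE),
                    class = "region_partition")
  sites <- scan_regions(rbind(as.data.frame(m1), as.data.frame(m2)), part,
                        scan_params(score_threshold = 60,
                                    energy_threshold = -5))
  expect_setequal(unique(sites$mirna_id), c("m1", "m2"))
})

test_that("raising thresholds never increases the number of sites", {
  set.seed(44)
  mirs <- generate_mirna_panel(4, 22, seed = 44)
  tg <- paste0(rand_dna(120), revcomp(mirs$seq[1]), rand_dna(120))
  part <- structure(list(pair_id = "p", sense_id = "s", antisense_id = "a",
                         pairing = data.frame(transcript_id = "s", start = 0L,
                                              end = nchar(tg), seq = tg),
                         nonpairing = NULL, overlap_len = nchar(tg),
                         score = 0, passes_filter = TRUE),
                    class = "region_partition")
  n_sites <- function(st, et)
    nrow(scan_regions(mirs, part, scan_params(score_threshold = st,
                                              energy_threshold = et)))
  base <- n_sites(40, -5)
  expect_gte(base, n_sites(90, -5))     # stricter score
  expect_gte(n_sites(40, -5), n_sites(40, -17))  # stricter energy
  expect_gte(base, n_sites(90, -17))
})

test_that("scan_regions recovers planted sites and labels region classes", {
  cfg <- synthetic_config(n_pairs = 4, overlap_len_range = c(120, 200),
                          flank_len_range = c(100, 160),
                          rate_pairing = 0.008, rate_nonpairing = 0.02,
                          mirna_panel_size = 5, seed = 14)
  ps <- generate_pair_set(cfg)
  parts <- partition_pairs(ps$records, ps$pairs)
  sites <- scan_regions(ps$mirnas, parts, scan_params())
  truth <- ps$truth$sites[ps$truth$sites$placed, ]
  for (k in seq_len(nrow(truth))) {
    hit <- sites[sites$transcript_id == truth$transcript_id[k] &
                   sites$mirna_id == truth$mirna_id[k] &
                   sites$start < truth$end[k] - 10 &
                   sites$end > truth$start[k] + 10, ]
    expect_gte(nrow(hit), 1L)
    expect_equal(unique(hit$region_class), truth$region_class[k])
  }
  # determinism
  expect_identical(sites, scan_regions(ps$mirnas, parts, scan_params()))
})

test_that("duplex_energy equals hand-summed nearest-neighbor totals on fixed helices", {
  # expected values summed by hand from the published stack table before
  # implementation: init +4.09, +0.45 per terminal A:U/G:U, +3.0 per
  # interior opening
  expect_equal(duplex_energy(list(target = "GCGCG", mirna = "CGCGC")),
               4.09 - 3.42 - 2.36 - 3.42 - 2.36, tolerance = 1e-9)  # -7.47
  expect_equal(duplex_energy(list(target = "AAAAA", mirna = "TTTTT")),
               4.09 + 0.45 + 0.45 - 4 * 0.93, tolerance = 1e-9)     # +1.27
  expect_equal(duplex_energy(list(target = "ACGTA", mirna = "TGCAT")),
               4.09 + 0.9 - 2.24 - 2.36 - 2.24 - 1.33, tolerance = 1e-9)
  expect_equal(duplex_energy(list(target = "GGTC", mirna = "CTAG")),
               4.09 - 1.53 - 1.36 - 2.35, tolerance = 1e-9)          # wobble
  expect_equal(duplex_energy(list(target = "GCATGCA", mirna = "CGTCCGT")),
               4.09 + 0.45 + 3.0 - 3.42 - 2.11 - 3.42 - 2.11,
               tolerance = 1e-9)                                     # loop
})

test_that("duplex_energy degenerate and monotonicity behavior", {
  expect_warning(e0 <- duplex_energy(list(target = "AAAA", mirna = "CCCC")),
                 "no paired positions")
  expect_equal(e0, 0)

  set.seed(55)
  mir <- rand_dna(22)
  perfect <- revcomp(mir)
  broken <- strsplit(perfect, "")[[1]]
  for (i in 10:12) broken[i] <- setdiff(c("A", "C", "G", "T"),
                                        c(broken[i],
                                          revcomp(substr(mir, 23 - i, 23 - i))))[1]
  e_perfect <- duplex_energy(list(target = perfect,
                                  mirna = paste(rev(strsplit(mir, "")[[1]]),
                                                collapse = "")))
  e_broken <- duplex_energy(list(target = paste(broken, collapse = ""),
                                 mirna = paste(rev(strsplit(mir, "")[[1]]),
                                               collapse = "")))
  expect_lt(e_perfect, e_broken)
})

test_that("the printed BACE1 exon-6 32-mer contains a miR-485-5p site", {
  # mature hsa-miR-485-5p (miRBase), supplied as input
  mir485 <- list(id = "hsa-miR-485-5p", seq = "AGAGGCUGGCCGUGAUGAAUUC")
  target <- "AAGCTGTAGTCAAATCCATCAAGGCAGCCTCC"
  h <- align_mirna(mir485, target, scan_params(score_threshold = 40))
  expect_gte(nrow(h), 1L)
  expect_gte(max(h$score), 90)
})
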