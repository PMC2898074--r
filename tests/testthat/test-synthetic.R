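test_that("miRNA panel generation is deterministic and respects bounds", {
  p1 <- generate_mirna_panel(10, 22, 0.5, seed = 1)
  p2 <- generate_mirna_panel(10, 22, 0.5, seed = 1)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10L)
  expect_true(all(nchar(p1$seq) == 22L))
  expect_false(identical(p1, generate_mirna_panel(10, 22, 0.5, seed = 2)))

  gc1 <- generate_mirna_panel(5, 30, gc = 0.999, seed = 3)
  expect_true(all(grepl("^[GC]+$", gc1$seq)))
  one <- generate_mirna_panel(1, 22, seed = 4)
  expect_equal(nrow(one), 1L)
  expect_error(generate_mirna_panel(0))
})

test_that("generate_pair_set geometry, ground truth and determinism", {
  cfg <- synthetic_config(n_pairs = 8, overlap_len_range = c(60, 120),
                          flank_len_range = c(80, 150), rate_pairing = 0.004,
                          rate_nonpairing = 0.012, mirna_panel_size = 5,
                          seed = 11)
  ps <- generate_pair_set(cfg)
  expect_identical(generate_pair_set(cfg)$records, ps$records)
  g <- ps$truth$geometry

  for (i in seq_len(nrow(g))) {
    s <- ps$records$seq[ps$records$id == g$sense_id[i]]
    a <- ps$records$seq[ps$records$id == g$antisense_id[i]]
    core_s <- substr(s, g$core_start_sense[i] + 1,
                     g$core_start_sense[i] + g$overlap_len[i])
    core_a <- substr(a, g$core_start_antisense[i] + 1,
                     g$core_start_antisense[i] + g$overlap_len[i])
    expect_identical(core_a, revcomp(core_s))
  }

  # every placed site is the exact reverse complement of its miRNA, inside
  # its declared region
  st <- ps$truth$sites[ps$truth$sites$placed, ]
  seqs <- setNames(ps$records$seq, ps$records$id)
  mir <- setNames(ps$mirnas$seq, ps$mirnas$id)
  for (k in seq_len(nrow(st))) {
    found <- substr(seqs[[st$transcript_id[k]]], st$start[k] + 1, st$end[k])
    expect_identical(found, revcomp(mir[[st$mirna_id[k]]]))
    gk <- g[g$pair_id == st$pair_id[k], ]
    if (st$region_class[k] == "pairing") {
      expect_true(st$start[k] >= gk$core_start_sense &&
                    st$end[k] <= gk$core_start_sense + gk$overlap_len)
    } else {
      inside_core <- st$transcript_id[k] == gk$sense_id &&
        st$start[k] < gk$core_start_sense + gk$overlap_len &&
        st$end[k] > gk$core_start_sense
      expect_false(inside_core)
    }
  }

  # zero rates -> empty ground truth
  cfg0 <- synthetic_config(n_pairs = 3, overlap_len_range = c(50, 60),
                           flank_len_range = c(50, 60), rate_pairing = 0,
                           rate_nonpairing = 0, seed = 2)
  expect_equal(nrow(generate_pair_set(cfg0)$truth$sites), 0L)
})

test_that("planted overlap-site totals follow the Poisson law", {
  # 200 pairs x 900-nt overlap at rate 0.01: mean 1800, sd sqrt(1800)
  cfg <- synthetic_config(n_pairs = 200, overlap_len_range = c(900, 900),
                          flank_len_range = c(30, 40), rate_pairing = 0.01,
                          rate_nonpairing = 0, mirna_panel_size = 5,
                          seed = 5)
  ps <- generate_pair_set(cfg)
  n_overlap <- sum(ps$truth$geometry$n_pairing)
  expect_equal(nrow(ps$truth$sites[ps$truth$sites$region_class == "pairing", ]),
               n_overlap)
  expect_lt(abs(n_overlap - 1800), 3 * sqrt(1800))
})

test_that("mono shuffle conserves composition; dinucleotide shuffle conserves dinucleotide counts", {
  expect_identical(shuffle_sequence("AAAA", "mono", seed = 1), "AAAA")
  expect_identical(shuffle_sequence("AAAA", "dinucleotide", seed = 1), "AAAA")
  expect_error(shuffle_sequence("ACGT", "bogus"))

  set.seed(31)
  for (r in 1:25) {
    s <- rand_dna(sample(5:120, 1))
    m <- shuffle_sequence(s, "mono")
    expect_identical(sort(strsplit(m, "")[[1]]), sort(strsplit(s, "")[[1]]))
    d <- shuffle_sequence(s, "dinucleotide")
    expect_identical(dinuc_counts(d), dinuc_counts(s))
  }
  # a fixed periodic sequence, against the brute-force counter
  d <- shuffle_sequence("ACGTACGTACGT", "dinucleotide", seed = 7)
  expect_identical(dinuc_counts(d), dinuc_counts("ACGTACGTACGT"))
  # seed determinism
  expect_identical(shuffle_sequence("ACGGTTACAGTT", "dinucleotide", seed = 3),
                   shuffle_sequence("ACGGTTACAGTT", "dinucleotide", seed = 3))
})

test_that("truth densities carry the planted counts and region lengths", {
  cfg <- synthetic_config(n_pairs = 5, overlap_len_range = c(80, 100),
                          flank_len_range = c(60, 90), rate_pairing = 0.01,
                          rate_nonpairing = 0.03, mirna_panel_size = 4,
                          seed = 9)
  ps <- suppressWarnings(generate_pair_set(cfg))
  td <- truth_densities(ps)
  expect_equal(nrow(td), 10L)
  g <- ps$truth$geometry
  i <- match(td$pair_id[td$region_class == "pairing"], g$pair_id)
  expect_equal(td$length_nt[td$region_class == "pairing"], g$overlap_len[i])
  expect_equal(td$density, td$site_count / td$length_nt)
})
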