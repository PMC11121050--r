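mut_at <- function(pos, chrom = "chr1", mclass = "SBS") {
  n <- length(pos)
  data.frame(line_id = rep("L", n), chrom = rep(chrom, n), pos = pos,
             ref = rep("A", n), alt = rep("G", n),
             mclass = rep(mclass, n), indel_len = rep(0L, n),
             stringsAsFactors = FALSE)
}

test_that("window binning uses 0-based half-open boundary arithmetic", {
  m <- mut_at(c(1, 999999, 1000000, 1000001))
  tr <- window_counts(m, "chr1", 3e6, 1e6)
  expect_equal(tr$counts, c(3, 1, 0))
  expect_equal(sum(tr$counts), 4)
  expect_error(window_counts(mut_at(5e6), "chr1", 3e6, 1e6), "beyond")
  # class filters and per-chromosome conservation on the shared fixture
  fx <- shared_fixture()
  tr_truth <- fx$planted$truth
  mm <- data.frame(line_id = tr_truth$line_id, chrom = tr_truth$chrom,
                   pos = tr_truth$pos, ref = tr_truth$ref, alt = tr_truth$alt,
                   mclass = tr_truth$class, indel_len = tr_truth$indel_len)
  for (ch in c("chr1", "chr2")) {
    t_all <- window_counts(mm, ch, 60000, 5000)
    t_sbs <- window_counts(mm, ch, 60000, 5000, "SBS")
    t_ind <- window_counts(mm, ch, 60000, 5000, "InDel")
    expect_equal(sum(t_all$counts), sum(tr_truth$chrom == ch))
    expect_equal(sum(t_sbs$counts) + sum(t_ind$counts), sum(t_all$counts))
  }
})

test_that("window frequencies use true window widths", {
  m <- mut_at(sample.int(1e6, 3300))
  tr <- window_counts(m, "chr1", 1e6, 1e6)
  expect_equal(window_frequency(tr), 3.3e-3)
  expect_equal(chrom_mean_frequency(tr), 3.3e-3)
  # terminal short window: 2.5 windows of 1e6 over 2.5e6 bp
  m2 <- mut_at(c(2400001, 2450000))
  tr2 <- window_counts(m2, "chr1", 2.5e6, 1e6)
  expect_equal(tr2$widths, c(1e6, 1e6, 5e5))
  expect_equal(window_frequency(tr2)[3], 2 / 5e5)
  expect_equal(window_frequency(tr2)[1], 0)
  expect_equal(chrom_mean_frequency(tr2), 2 / 2.5e6)
})

test_that("HF calling flags, merges and measures fold enrichment", {
  # one 1 Mb window at 3.3e-3/bp on a chromosome whose mean is ~6.3e-5
  L <- round(3300 / 6.3e-5)        # total 3300 mutations over L bp
  m <- mut_at(sample.int(1e6, 3300))
  tr <- window_counts(m, "chr1", L, 1e6)
  hf <- call_hf_regions(tr, fold_threshold = 20)
  expect_equal(nrow(hf), 1)
  expect_equal(hf$start, 0)
  expect_equal(hf$end, 1e6)
  expect_equal(hf$fold, (3300 / 1e6) / (3300 / L), tolerance = 1e-9)
  expect_gt(hf$fold, 52)           # ~52.4x
  expect_equal(hf$fraction_of_total, 1)

  # uniform counts produce no HF call; empty chromosome returns empty
  set.seed(5)
  mu <- mut_at(sample.int(3e6, 3000))
  expect_equal(nrow(call_hf_regions(window_counts(mu, "chr1", 3e6, 1e5), 20)), 0)
  expect_equal(nrow(call_hf_regions(window_counts(mut_at(integer()), "chr1",
                                                  1e6, 1e5), 20)), 0)

  # adjacent flagged windows merge into one region
  m3 <- mut_at(c(sample.int(1e5, 400), 1e5 + sample.int(1e5, 400),
                 sample.int(98e5, 40) + 2e5))
  tr3 <- window_counts(m3, "chr1", 1e7, 1e5)
  hf3 <- call_hf_regions(tr3, 20)
  expect_equal(nrow(hf3), 1)
  expect_equal(c(hf3$start, hf3$end), c(0, 2e5))
  expect_error(call_hf_regions(tr3, 1), "fold_threshold")
})

test_that("a planted 50x hotspot is detected and overlaps the truth interval", {
  g <- generate_genome(1, 1000000, 0, seed = 31)
  hs <- hotspot_spec("chr1", 200000, 210000, 50)
  p <- plant_mutations(g$genome, g$annotation,
                       spectrum_params(indel_fraction = 0.118), hs,
                       n_mutations = 5000, seed = 31, n_background = 0)
  mm <- data.frame(line_id = "L", chrom = p$truth$chrom, pos = p$truth$pos,
                   ref = p$truth$ref, alt = p$truth$alt,
                   mclass = p$truth$class, indel_len = p$truth$indel_len)
  tr <- window_counts(mm, "chr1", 1e6, 1e4)
  hf <- call_hf_regions(tr, 20)
  expect_gt(nrow(hf), 0)
  expect_true(any(hf$start < 210000 & hf$end > 200000))

  # scale consistency: every coarse HF region contains a flagged fine window
  tr_c <- window_counts(mm, "chr1", 1e6, 1e5)
  hf_c <- call_hf_regions(tr_c, 20)
  hf_f <- call_hf_regions(window_counts(mm, "chr1", 1e6, 1e4), 20)
  for (i in seq_len(nrow(hf_c))) {
    expect_true(any(hf_f$start < hf_c$end[i] & hf_f$end > hf_c$start[i]))
  }
})

test_that("colocalization reports Jaccard and a hypergeometric tail", {
  hf1 <- data.frame(chrom = "chr1", start = c(0, 3e5), end = c(1e5, 4e5),
                    mclass = "SBS", n_mut = 10, fold = 30,
                    fraction_of_total = 0.1)
  # identical sets
  co <- colocalization(hf1, transform(hf1, mclass = "InDel"), 3e6, 1e5)
  expect_equal(co$jaccard, 1)
  expect_equal(co$shared, 2)
  # disjoint sets
  hf2 <- transform(hf1, start = c(1e5, 5e5), end = c(2e5, 6e5))
  co2 <- colocalization(hf1, hf2, 3e6, 1e5)
  expect_equal(co2$jaccard, 0)
  expect_equal(co2$shared, 0)
  expect_equal(co2$p_hyper, 1)      # P(X >= 0) = 1
  # empty vs empty
  co3 <- colocalization(hf1[0, ], hf1[0, ], 3e6, 1e5)
  expect_true(is.na(co3$jaccard))
  # geometry mismatches error
  expect_error(colocalization(transform(hf1, start = start + 1), hf1, 3e6, 1e5),
               "geometry")
  expect_error(colocalization(hf1, hf2, 3e5, 1e5), "exceed")
})

test_that("the hypergeometric tail equals exhaustive enumeration", {
  # 3-and-3 flagged among 30 windows, >= 2 shared
  p_enum <- oracle_overlap_tail(n = 30, a = 3, b = 3, k = 2)
  hf_a <- data.frame(chrom = "c", start = c(0, 1e5, 2e5),
                     end = c(1e5, 2e5, 3e5), mclass = "SBS", n_mut = 1,
                     fold = 30, fraction_of_total = 0.1)
  hf_b <- data.frame(chrom = "c", start = c(0, 1e5, 5e5),
                     end = c(1e5, 2e5, 6e5), mclass = "InDel", n_mut = 1,
                     fold = 30, fraction_of_total = 0.1)
  co <- colocalization(hf_a, hf_b, 30e5, 1e5)
  expect_equal(co$shared, 2)
  expect_equal(co$p_hyper, p_enum, tolerance = 1e-12)
})
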