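gb <- genome_build("chr1", 100e6)

normals_with_gain <- function(n_with, n_without, a = 10e6, b = 20e6,
                              log2 = 0.6) {
  c(lapply(seq_len(n_with), function(i)
      cn_profile(sprintf("NW%02d", i), data.frame(
        chrom = "chr1", start = c(0, a, b), end = c(a, b, 100e6),
        n_probes = c(100, 50, 100), log2 = c(0, log2, 0)),
        genome = gb)),
    lapply(seq_len(n_without), function(i)
      flat_profile(sprintf("NF%02d", i), gb)))
}

test_that("CNP derivation applies the strict >5% rule", {
  expect_error(derive_cnp_intervals(list()), "without normals")
  # no normal exceeds |0.3|: empty set
  quiet <- lapply(1:5, function(i) flat_profile(paste0("N", i), gb,
                                                log2 = 0.1))
  expect_equal(nrow(derive_cnp_intervals(quiet)), 0)
  # 2/20 = 10% > 5%: one CNP interval at the shared locus
  cnp <- derive_cnp_intervals(normals_with_gain(2, 18))
  expect_equal(nrow(cnp), 1)
  expect_equal(cnp$start, 10e6)
  expect_equal(cnp$end, 20e6)
  expect_equal(cnp$provenance, "cnp")
  # 1/20 = 5% exactly: NOT > 5%, so empty (boundary of the quoted rule)
  expect_equal(nrow(derive_cnp_intervals(normals_with_gain(1, 19))), 0)
})

test_that("CNP masking removes regions and splits segments", {
  cnp <- cn_regions("chr1", 14e6, 20e6, "cnp1", "gain", "cnp")
  regs <- cn_regions("chr1", c(5e6, 30e6), c(15e6, 40e6),
                     c("r1", "r2"), "gain")
  # r1 overlaps the CNP by 1 Mb -> removed; r2 untouched
  kept <- mask_cnp(regs, cnp)
  expect_equal(kept$label, "r2")
  # 1-bp overlap suffices
  cnp1 <- cn_regions("chr1", 14999999, 20e6, "c", "gain", "cnp")
  reg1 <- cn_regions("chr1", 5e6, 15e6, "r", "gain")
  expect_equal(nrow(mask_cnp(reg1, cnp1)), 0)
  # empty CNP set: identity
  empty <- cn_regions(character(), numeric(), numeric(), character(),
                      character())
  expect_equal(mask_cnp(regs, empty), regs)

  # segment [0,30) minus CNP [10,20) -> [0,10) and [20,30), same log2,
  # probes prorated by length
  p <- make_profile("S", list(c(0, 30e6, 300, 0.7)), genome = gb)
  cnp2 <- cn_regions("chr1", 10e6, 20e6, "c", "gain", "cnp")
  m <- mask_cnp(p, cnp2)
  expect_equal(m$start, c(0, 20e6))
  expect_equal(m$end, c(10e6, 30e6))
  expect_equal(m$log2, c(0.7, 0.7))
  expect_equal(m$n_probes, c(100, 100))
  expect_silent(validate_profile(m))
})

test_that("small-segment merging absorbs into the closest neighbour", {
  # spec'd example: log2 (0.0, 0.9, 0.05), probes (100, 4, 120), min 10
  # -> middle absorbed rightward (|0.9-0.05| = 0.85 < |0.9-0.0| = 0.90)
  p <- make_profile("S", list(c(0, 50, 100, 0.0),
                              c(50, 60, 4, 0.9),
                              c(60, 120, 120, 0.05)), genome = NULL)
  m <- merge_small_segments(p, 10)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(0, 50))
  expect_equal(m$end, c(50, 120))
  expect_equal(m$log2, c(0.0, 0.05))
  expect_equal(m$n_probes, c(100, 124))

  # all segments above threshold: identity
  q <- make_profile("S", list(c(0, 50, 100, 0.1), c(50, 90, 50, 0.4)))
  expect_equal(as.data.frame(merge_small_segments(q, 10)),
               as.data.frame(q))
  # lone small whole-chromosome segment is retained
  r <- make_profile("S", list(c(0, 100, 3, 0.2)))
  expect_equal(as.data.frame(merge_small_segments(r, 10)),
               as.data.frame(r))
  # neighbour tie absorbs leftward (deterministic)
  t1 <- make_profile("S", list(c(0, 10, 50, 0.5), c(10, 20, 2, 0.0),
                               c(20, 30, 50, 0.5)))
  mt <- merge_small_segments(t1, 10)
  expect_equal(mt$end, c(20, 30))
  expect_equal(mt$n_probes, c(52, 50))
})

test_that("merging conserves coverage and is a fixed point", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    cuts <- sort(sample(1:999, k - 1))
    bnd <- c(0, cuts, 1000) * 1e5
    p <- cn_profile("S", data.frame(
      chrom = "chr1", start = bnd[-(k + 1)], end = bnd[-1],
      n_probes = sample(c(1:8, 50:200), k, replace = TRUE),
      log2 = rnorm(k, 0, 0.5)), genome = gb)
    m <- merge_small_segments(p, 10)
    expect_silent(validate_profile(m))
    expect_equal(sum(m$end - m$start), sum(p$end - p$start))
    expect_equal(sum(m$n_probes), sum(p$n_probes))
    expect_true(nrow(m) == 1 || all(m$n_probes >= 10))
    m2 <- merge_small_segments(m, 10)
    expect_identical(as.data.frame(m2), as.data.frame(m))
  }
})

test_that("state calling uses strict thresholds with nested flags", {
  p <- make_profile("S", list(
    c(0, 10, 5, 0.3),    # exactly at the threshold: neutral
    c(10, 20, 5, -1.2),  # loss and hd
    c(20, 30, 5, 0.85),  # gain, >0.6, >0.8, not >1
    c(30, 40, 5, -0.3),  # neutral (strict <)
    c(40, 50, 5, 1.01)))
  st <- call_states(p)
  expect_equal(st$state,
               c("neutral", "loss", "gain", "neutral", "gain"))
  expect_false(st$`gain_0.6`[1])
  expect_true(st$hd[2])
  expect_equal(unlist(st[3, c("gain_0.6", "gain_0.8", "gain_1.0")],
                      use.names = FALSE), c(TRUE, TRUE, FALSE))
  expect_true(all(st[5, c("gain_0.6", "gain_0.8", "gain_1.0")] == TRUE))
  # monotone flag nesting on random fixtures
  set.seed(22)
  rp <- make_profile("R", lapply(1:50, function(i)
    c((i - 1) * 10, i * 10, 20, rnorm(1, 0, 0.8))))
  rs <- call_states(rp)
  expect_true(all(rs$`gain_1.0` <= rs$`gain_0.8`))
  expect_true(all(rs$`gain_0.8` <= rs$`gain_0.6`))
  expect_true(all(rs$`gain_0.6` <= (rs$state == "gain")))
  expect_true(all(rs$hd <= (rs$state == "loss")))
})

test_that("planted CNPs are recovered from 50 simulated normals", {
  cnps <- data.frame(chrom = c("chr1", "chr1"),
                     start = c(20e6, 70e6), end = c(22e6, 71e6),
                     pop_freq = c(0.3, 0.2), log2 = c(0.5, -0.6))
  cfg <- mini_config(0, n_normals = 50, cnp_specs = cnps, seed = 23)
  sim <- simulate_cohort(cfg)
  found <- derive_cnp_intervals(sim$normals)
  jaccard <- function(a_start, a_end, b) {
    gr_a <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(a_start + 1, a_end))
    gr_b <- GenomicRanges::GRanges(b$chrom,
      IRanges::IRanges(b$start + 1, b$end))
    inter <- sum(GenomicRanges::width(
      GenomicRanges::intersect(gr_a, gr_b)))
    uni <- sum(GenomicRanges::width(GenomicRanges::union(gr_a, gr_b)))
    inter / uni
  }
  expect_gte(jaccard(cnps$start, cnps$end, found), 0.9)
})
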