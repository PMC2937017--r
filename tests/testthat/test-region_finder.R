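test_that("frequency track counts on the breakpoint-union partition", {
  gb <- toy_genome()
  one <- cohort_with_gain(1, 1, 10e6, 20e6, log2 = 0.8, genome = gb)
  tr <- frequency_track(one, "gain", 0.3)
  core <- tr[tr$start == 10e6, ]
  expect_equal(core$fraction, 1)
  expect_true(all(tr$fraction[tr$start != 10e6] == 0))

  # 3 of 10 samples share a gain > 1 over a common core
  ten <- cohort_with_gain(10, 3, 10e6, 20e6, log2 = 1.2, genome = gb)
  t10 <- frequency_track(ten, "gain", 1.0)
  expect_equal(t10$fraction[t10$start == 10e6], 0.3)

  # pointwise monotone non-increasing in threshold
  for (amp in c(0.3, 0.6, 0.8)) {
    lo <- frequency_track(ten, "gain", amp)
    hi <- frequency_track(ten, "gain", 1.0)
    expect_true(all(hi$count <= lo$count))
  }
  expect_error(frequency_track(list(), "gain", 0.3), "empty")
  expect_error(frequency_track(ten, "gain", -0.3), "positive")
})

test_that("frequency tracks export as bedGraph", {
  ten <- cohort_with_gain(10, 3, 10e6, 20e6, log2 = 1.2)
  tr <- frequency_track(ten, "gain", 0.3)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  ln <- readLines(path)
  expect_match(ln[1], "^track type=bedGraph")
  expect_equal(length(ln), nrow(tr) + 1)
  core <- strsplit(ln[-1], "\t")[[which(tr$start == 10e6)]]
  expect_equal(as.numeric(core[4]), 0.3)
})

test_that("tier rules convert fractions to ceilinged counts", {
  rules <- default_tier_rules()
  r06 <- rules[rules$tier == "gain_0.6", ]
  # at n = 398 the 10% rule means 40 or more samples
  expect_equal(cnassoc:::.rule_min_count(r06, 398), 40)
  expect_equal(cnassoc:::.rule_min_count(r06, 10), 1)
  # HD rule: absolute count of 4
  expect_equal(cnassoc:::.rule_min_count(rules[rules$tier == "hd", ],
                                         398), 4)
})

test_that("tier regions are maximal qualifying intervals", {
  gb <- toy_genome()
  ten <- cohort_with_gain(10, 3, 10e6, 20e6, log2 = 1.2, genome = gb)
  rules <- default_tier_rules()
  tracks <- lapply(seq_len(nrow(rules)), function(i)
    frequency_track(ten, rules$direction[i], rules$amplitude[i]))
  regs <- tier_regions(tracks, rules)
  # 3/10 = 30% qualifies every gain tier incl. >1 at 2.5% (ceil -> 1)
  r1 <- regs[regs$tier == "gain_1.0", ]
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 10e6)
  expect_equal(r1$end, 20e6)
  expect_equal(r1$aber_type, "gain")
  expect_equal(r1$provenance, "tier")
  expect_equal(r1$max_count, 3)
  # flat cohort: no regions at all
  flat <- lapply(1:5, function(i) flat_profile(paste0("F", i), gb))
  ft <- lapply(seq_len(nrow(rules)), function(i)
    frequency_track(flat, rules$direction[i], rules$amplitude[i]))
  expect_equal(nrow(tier_regions(ft, rules)), 0)
  # rule without matching track errors
  expect_error(tier_regions(tracks[1:2], rules), "no track")
})

test_that("frequency tracks nest pointwise across amplitudes", {
  # the breakpoint-union partition is shared across thresholds, so the
  # per-interval counts must be monotone non-increasing in amplitude;
  # tier regions from a higher rule then always sit under lower-tier
  # frequency mass
  sim <- simulate_cohort(default_sim_config(80, 0, seed = 31))
  amps <- c(0.3, 0.6, 0.8, 1.0)
  tracks <- lapply(amps, function(a)
    frequency_track(sim$tumours, "gain", a))
  for (i in 2:4)
    expect_true(all(tracks[[i]]$count <= tracks[[i - 1]]$count))
})

test_that("aberration matrix scores overlap with direction matching", {
  gb <- toy_genome()
  gain_p <- make_profile("G", list(c(0, 10e6, 100, 0.9),
                                   c(10e6, 100e6, 900, 0)),
                         genome = gb)
  loss_p <- make_profile("L", list(c(0, 10e6, 100, -0.9),
                                   c(10e6, 100e6, 900, 0)),
                         genome = gb)
  flat_p <- flat_profile("F", gb)
  regs <- cn_regions("chr1", c(5e6, 50e6), c(15e6, 60e6),
                     c("rg", "rl"), c("gain", "loss"))
  X <- build_matrix(list(gain_p, loss_p, flat_p), regs)
  # loss segment over a gain-type region scores 0, and vice versa
  expect_equal(X["G", "rg"], 1L)
  expect_equal(X["L", "rg"], 0L)
  expect_equal(unname(X["F", ]), c(0L, 0L))  # flat genome: all-zero row
  # 1-bp overlap of a qualifying gain counts as presence
  tiny <- cn_regions("chr1", 9999999, 30e6, "edge", "gain")
  X2 <- build_matrix(list(gain_p), tiny)
  expect_equal(X2["G", "edge"], 1L)
  # matrix column sum respects the tier rule that defined a region
  ten <- cohort_with_gain(10, 3, 10e6, 20e6, log2 = 1.2, genome = gb)
  r <- cn_regions("chr1", 10e6, 20e6, "core", "gain")
  r$amplitude <- 1.0
  X3 <- build_matrix(ten, r, use_tier_amplitude = TRUE)
  expect_equal(sum(X3[, "core"]), 3)
})

test_that("pair filtering removes same-broad and CNP pairs", {
  regs <- cn_regions("chr1", c(0, 20e6, 40e6, 60e6) + 1e6,
                     c(10e6, 30e6, 50e6, 70e6),
                     c("r1", "r2", "r3", "r4"), "gain")
  all_pairs <- filter_region_pairs(regs)
  expect_equal(nrow(all_pairs), choose(4, 2))
  # r1 and r2 inside one broad region: their pair is excluded
  broad <- cn_regions("chr1", 0, 35e6, "broad1", "gain", "broad")
  fp <- filter_region_pairs(regs, broad_regions = broad)
  expect_equal(nrow(fp), 5)
  expect_false(any(fp$a == "r1" & fp$b == "r2"))
  # a region overlapping a CNP by 1 bp loses all its pairs
  cnp <- cn_regions("chr1", 50e6 - 1, 55e6, "c", "gain", "cnp")
  fc <- filter_region_pairs(regs, cnp = cnp)
  expect_equal(nrow(fc), 3)
  expect_false(any(fc$a == "r3" | fc$b == "r3"))
})

test_that("planted regions are recovered at the 30% rule (n = 200)", {
  sim <- simulate_cohort(default_sim_config(200, 0, seed = 32))
  rules <- default_tier_rules()
  base <- rules[rules$amplitude %in% c(0.3, -0.3), ]
  tracks <- lapply(seq_len(nrow(base)), function(i)
    frequency_track(sim$tumours, base$direction[i], base$amplitude[i]))
  regs <- tier_regions(tracks, base)
  planted <- sim$regions[sim$regions$label %in%
                           c("gain_3q26", "gain_8q24", "loss_17q12",
                             "loss_Xq"), ]
  for (i in seq_len(nrow(planted))) {
    cand <- regs[regs$chrom == planted$chrom[i] &
                   regs$aber_type == planted$aber_type[i], ]
    expect_gte(nrow(cand), 1)
    inter <- min(cand$end, planted$end[i]) -
      max(cand$start, planted$start[i])
    union <- max(cand$end, planted$end[i]) -
      min(cand$start, planted$start[i])
    expect_gte(inter / union, 0.8)
  }
})
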