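#' Genome-wide aberration frequency track
#'
#' Overlaps all samples' segments to form the breakpoint-union partition
#' (one interval per stretch between any two breakpoints observed in the
#' cohort) and, on each interval, counts the samples whose covering segment
#' passes the amplitude threshold: `log2 > amplitude` for gains,
#' `log2 < amplitude` for losses (strict).
#'
#' @param profiles list of [cn_profile()] (>= 1).
#' @param direction `"gain"` or `"loss"`.
#' @param amplitude log2 threshold; positive for gains, negative for
#'   losses.
#' @return data.frame of class `frequency_track` with columns `chrom`,
#'   `start`, `end`, `count`, `fraction`; attributes `n_samples`,
#'   `direction`, `amplitude`.
#' @export
frequency_track <- function(profiles, direction = c("gain", "loss"),
                            amplitude) {
  direction <- match.arg(direction)
  if (length(profiles) == 0) stop("empty cohort")
  if (direction == "gain" && amplitude <= 0)
    stop("gain amplitude must be positive")
  if (direction == "loss" && amplitude >= 0)
    stop("loss amplitude must be negative")
  n <- length(profiles)
  gr <- .profiles_gr(profiles)
  d <- GenomicRanges::disjoin(gr)
  lg <- S4Vectors::mcols(gr)$log2
  pass <- if (direction == "gain") lg > amplitude else lg < amplitude
  hits <- GenomicRanges::findOverlaps(d, gr[pass])
  cnt <- tabulate(S4Vectors::queryHits(hits), nbins = length(d))
  out <- .gr_df(d)
  out$count <- cnt
  out$fraction <- cnt / n
  structure(out, n_samples = n, direction = direction,
            amplitude = amplitude,
            class = c("frequency_track", "data.frame"))
}

#' Write a frequency track as bedGraph
#'
#' Four-column bedGraph (chrom, start, end, fraction) with a `track`
#' declaration line, loadable in genome browsers.
#'
#' @param track a [frequency_track()].
#' @param path output path.
#' @param name track name for the declaration line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path,
                           name = sprintf("%s_%g",
                                          attr(track, "direction"),
                                          attr(track, "amplitude"))) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(paste(track$chrom,
                   sprintf("%.0f", track$start),
                   sprintf("%.0f", track$end),
                   format(track$fraction, digits = 6), sep = "\t"), con)
  invisible(path)
}

#' Default tiered region-calling rules
#'
#' The tier ladder used for reporting recurrent aberrations: gains at
#' >0.3 log2 in at least 30% of samples, >0.6 in 10%, >0.8 in 5%, >1 in
#' 2.5%; losses at <-0.3 in 30%; homozygous deletions (<-1) in at least 4
#' samples regardless of cohort size.  Fractions are converted to counts
#' by ceiling ("at least" semantics: at n = 398 the 10% rule means 40 or
#' more samples).  When both a fraction and a count are given the rule
#' fires if either is met (OR semantics, used for the HD rule).
#'
#' @return data.frame with columns `direction`, `amplitude`,
#'   `min_fraction`, `min_count`, `tier`.
#' @export
default_tier_rules <- function() {
  data.frame(
    direction = c("gain", "gain", "gain", "gain", "loss", "loss"),
    amplitude = c(0.3, 0.6, 0.8, 1.0, -0.3, -1.0),
    min_fraction = c(0.30, 0.10, 0.05, 0.025, 0.30, NA),
    min_count = c(NA, NA, NA, NA, NA, 4),
    tier = c("gain_0.3", "gain_0.6", "gain_0.8", "gain_1.0",
             "loss_0.3", "hd"),
    stringsAsFactors = FALSE)
}

# effective minimum count for one rule at cohort size n
.rule_min_count <- function(rule, n) {
  cand <- c(if (!is.na(rule$min_fraction)) ceiling(rule$min_fraction * n),
            if (!is.na(rule$min_count)) rule$min_count)
  if (!length(cand)) stop("tier rule with neither fraction nor count")
  min(cand)  # OR semantics when both present
}

#' Call tiered aberration regions from frequency tracks
#'
#' For each rule, the maximal runs of contiguous breakpoint-union intervals
#' whose sample count meets the rule's threshold become regions
#' (provenance `"tier"`).  Each region also carries the peak summit: the
#' sub-interval of maximal count (leftmost on ties), reported in
#' `peak_start`/`peak_end`.
#'
#' @param tracks named list of [frequency_track()] objects; names are
#'   ignored, each rule is matched to the track with its direction and
#'   amplitude.
#' @param rules rule table as from [default_tier_rules()].
#' @param n_samples cohort size (taken from the tracks if missing).
#' @return A [cn_regions()] table with extra columns `tier`, `amplitude`,
#'   `max_count`, `peak_start`, `peak_end`.
#' @export
tier_regions <- function(tracks, rules = default_tier_rules(),
                         n_samples = NULL) {
  if (inherits(tracks, "frequency_track")) tracks <- list(tracks)
  out <- NULL
  for (k in seq_len(nrow(rules))) {
    rule <- rules[k, ]
    tr <- NULL
    for (t in tracks)
      if (attr(t, "direction") == rule$direction &&
          isTRUE(all.equal(attr(t, "amplitude"), rule$amplitude)))
        tr <- t
    if (is.null(tr))
      stop("no track for rule ", rule$tier, " (", rule$direction, " at ",
           rule$amplitude, ")")
    n <- if (is.null(n_samples)) attr(tr, "n_samples") else n_samples
    mc <- .rule_min_count(rule, n)
    q <- tr[tr$count >= mc, , drop = FALSE]
    if (!nrow(q)) next
    # fuse contiguous qualifying intervals into maximal regions
    merged <- GenomicRanges::reduce(.gr(q$chrom, q$start, q$end))
    mdf <- .gr_df(merged)
    hits <- GenomicRanges::findOverlaps(merged, .gr(q$chrom, q$start,
                                                    q$end))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    peak <- vapply(seq_len(nrow(mdf)), function(i) {
      j <- sh[qh == i]
      j[which.max(q$count[j])]
    }, integer(1))
    reg <- cn_regions(mdf$chrom, mdf$start, mdf$end,
                      label = sprintf("%s_%s:%.2f-%.2fMb", rule$tier,
                                      mdf$chrom, mdf$start / 1e6,
                                      mdf$end / 1e6),
                      aber_type = rule$direction, provenance = "tier")
    reg$tier <- rule$tier
    reg$amplitude <- rule$amplitude
    reg$max_count <- vapply(seq_len(nrow(mdf)), function(i)
      max(q$count[sh[qh == i]]), numeric(1))
    reg$peak_start <- q$start[peak]
    reg$peak_end <- q$end[peak]
    out <- rbind(out, as.data.frame(reg))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character(),
                      aber_type = character(), provenance = character(),
                      tier = character(), amplitude = numeric(),
                      max_count = numeric(), peak_start = numeric(),
                      peak_end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cn_regions", "data.frame")
  out
}

#' Build the binary sample-by-region aberration matrix
#'
#' `X[t, i] = 1` iff sample `t` has at least one segment overlapping region
#' `i` by at least 1 bp whose state matches the region's `aber_type` at
#' the universal threshold (gain: `log2 > thresholds$gain`; loss:
#' `log2 < thresholds$loss`).  Any overlap counts as presence; gain-type
#' regions score gains only and loss-type regions score losses only.  With
#' `use_tier_amplitude = TRUE` and regions carrying an `amplitude` column,
#' presence is instead scored at each region's own tier amplitude
#' (sensitivity analysis).
#'
#' @param profiles list of [cn_profile()].
#' @param regions a [cn_regions()] table (non-empty, unique labels).
#' @param thresholds a [call_thresholds()].
#' @param use_tier_amplitude score at the region's own amplitude instead
#'   of the base threshold.
#' @return binary matrix, rows = samples, columns = region labels.
#' @export
build_matrix <- function(profiles, regions,
                         thresholds = call_thresholds(),
                         use_tier_amplitude = FALSE) {
  if (nrow(regions) == 0) stop("regions must be non-empty")
  stopifnot(!anyDuplicated(regions$label))
  samples <- vapply(profiles, sample_id, character(1))
  gr <- .profiles_gr(profiles)
  lg <- S4Vectors::mcols(gr)$log2
  reg_gr <- .gr(regions$chrom, regions$start, regions$end)
  X <- matrix(0L, nrow = length(profiles), ncol = nrow(regions),
              dimnames = list(samples, regions$label))
  for (i in seq_len(nrow(regions))) {
    thr <- if (use_tier_amplitude && "amplitude" %in% names(regions))
      regions$amplitude[i]
    else if (regions$aber_type[i] == "gain") thresholds$gain
    else thresholds$loss
    pass <- if (regions$aber_type[i] == "gain") lg > thr else lg < thr
    hits <- GenomicRanges::findOverlaps(reg_gr[i], gr[pass])
    hit_samples <- unique(
      S4Vectors::mcols(gr[pass])$sample[S4Vectors::subjectHits(hits)])
    X[match(hit_samples, samples), i] <- 1L
  }
  X
}

#' Admissible region pairs for association testing
#'
#' All unordered pairs of regions except (a) pairs in which both regions
#' fall inside one broad region (physically linked loci are not
#' independent, violating the test's assumption) and (b) pairs in which
#' either region overlaps a CNP interval by at least 1 bp (inherited
#' variation, not somatic).
#'
#' @param regions a [cn_regions()] table with unique labels.
#' @param broad_regions optional [cn_regions()] of broad regions.
#' @param cnp optional [cn_regions()] of CNP intervals.
#' @return data.frame with columns `a`, `b` (region labels, a < b in
#'   region-table order).
#' @export
filter_region_pairs <- function(regions, broad_regions = NULL,
                                cnp = NULL) {
  stopifnot(!anyDuplicated(regions$label))
  k <- nrow(regions)
  if (k < 2)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(k, 2)
  keep <- rep(TRUE, ncol(idx))
  reg_gr <- .gr(regions$chrom, regions$start, regions$end)
  if (!is.null(cnp) && nrow(cnp)) {
    cnp_hit <- GenomicRanges::countOverlaps(
      reg_gr, .gr(cnp$chrom, cnp$start, cnp$end)) > 0
    keep <- keep & !(cnp_hit[idx[1, ]] | cnp_hit[idx[2, ]])
  }
  if (!is.null(broad_regions) && nrow(broad_regions)) {
    broad_gr <- .gr(broad_regions$chrom, broad_regions$start,
                    broad_regions$end)
    within <- GenomicRanges::findOverlaps(reg_gr, broad_gr,
                                          type = "within")
    # broad-region membership per region, as a list of broad indices
    memb <- split(S4Vectors::subjectHits(within),
                  factor(S4Vectors::queryHits(within), levels = seq_len(k)))
    same_broad <- vapply(seq_len(ncol(idx)), function(j) {
      length(intersect(memb[[idx[1, j]]], memb[[idx[2, j]]])) > 0
    }, logical(1))
    keep <- keep & !same_broad
  }
  data.frame(a = regions$label[idx[1, keep]],
             b = regions$label[idx[2, keep]], stringsAsFactors = FALSE)
}
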