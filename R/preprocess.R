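#' Aberration-calling thresholds
#'
#' The universal log2 thresholds used throughout: a segment is called a
#' gain when `log2 > gain` and a loss when `log2 < loss` (strict
#' inequalities).  High-amplitude gain tiers flag `log2 > 0.6 / 0.8 / 1.0`
#' and homozygous deletions flag `log2 < hd`.  `min_probes` gives the
#' platform-specific minimum probe count below which segments are merged
#' away ([merge_small_segments()]).
#'
#' @param gain gain threshold (default +0.3).
#' @param loss loss threshold (default -0.3).
#' @param high_tiers increasing vector of high-gain tier thresholds.
#' @param hd homozygous-deletion threshold (default -1.0, must be < loss).
#' @param min_probes named vector of per-platform minimum probe counts.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(gain = 0.3, loss = -0.3,
                            high_tiers = c(0.6, 0.8, 1.0), hd = -1.0,
                            min_probes = c(snp6 = 10, k500 = 5)) {
  stopifnot(gain > 0, loss < 0, hd < loss,
            all(diff(c(gain, high_tiers)) > 0))
  structure(list(gain = gain, loss = loss, high_tiers = high_tiers,
                 hd = hd, min_probes = min_probes),
            class = "call_thresholds")
}

#' Derive copy-number-polymorphism intervals from normal samples
#'
#' Inherited copy-number polymorphisms (CNPs) appear in normal genomes and
#' must be excluded from somatic analysis.  On the breakpoint-union
#' partition of all normal profiles, the fraction of normals carrying an
#' aberrant segment (`|log2| > call`) over each interval is computed;
#' maximal intervals where that fraction strictly exceeds `freq_threshold`
#' (adjacent qualifying intervals merged) become CNP intervals.
#'
#' This interval-level derivation stands in for probe-level exclusion when
#' only segmented input is available.
#'
#' @param normals list of [cn_profile()] from normal samples.
#' @param freq_threshold population-frequency cutoff (strict >; default
#'   0.05).
#' @param call absolute log2 threshold defining an aberrant normal segment
#'   (default 0.3).
#' @return A [cn_regions()] table with `provenance = "cnp"`; `aber_type`
#'   is the majority direction among covering aberrant normal segments.
#' @export
derive_cnp_intervals <- function(normals, freq_threshold = 0.05,
                                 call = 0.3) {
  if (length(normals) == 0)
    stop("cannot derive CNPs without normals")
  n <- length(normals)
  gr <- .profiles_gr(normals)
  ab <- gr[abs(S4Vectors::mcols(gr)$log2) > call]
  empty <- cn_regions(character(), numeric(), numeric(), character(),
                      character())
  if (length(ab) == 0) return(empty)
  d <- GenomicRanges::disjoin(ab)
  hits <- GenomicRanges::findOverlaps(d, ab)
  cnt <- tabulate(S4Vectors::queryHits(hits), nbins = length(d))
  gain_hits <- S4Vectors::mcols(ab)$log2[S4Vectors::subjectHits(hits)] > 0
  gains <- tabulate(S4Vectors::queryHits(hits)[gain_hits],
                    nbins = length(d))
  keep <- cnt / n > freq_threshold
  if (!any(keep)) return(empty)
  kept <- d[keep]
  merged <- GenomicRanges::reduce(kept)
  # majority direction over each merged interval (tie -> gain)
  mh <- GenomicRanges::findOverlaps(merged, kept)
  g <- tapply(gains[keep][S4Vectors::subjectHits(mh)],
              S4Vectors::queryHits(mh), sum)
  tot <- tapply(cnt[keep][S4Vectors::subjectHits(mh)],
                S4Vectors::queryHits(mh), sum)
  df <- .gr_df(merged)
  cn_regions(df$chrom, df$start, df$end,
             label = sprintf("cnp_%s:%d-%d", df$chrom,
                             as.integer(df$start / 1e3),
                             as.integer(df$end / 1e3)),
             aber_type = ifelse(g >= tot - g, "gain", "loss"),
             provenance = "cnp")
}

#' Mask CNP intervals out of regions or profiles
#'
#' For a region table, any region overlapping a CNP interval by at least
#' 1 bp is removed.  For a profile, segments are intersected with the
#' complement of the CNP intervals (split where needed); probe counts are
#' prorated by retained length and floored at 1; log2 values are kept.
#'
#' @param x a [cn_regions()] table or a [cn_profile()].
#' @param cnp a [cn_regions()] table of CNP intervals (may be empty).
#' @return Object of the same type as `x`, filtered.
#' @export
mask_cnp <- function(x, cnp) {
  if (is.null(cnp) || nrow(cnp) == 0) return(x)
  cnp_gr <- .gr(cnp$chrom, cnp$start, cnp$end)
  if (inherits(x, "cn_profile")) {
    seg_gr <- .gr(x$chrom, x$start, x$end)
    hits <- GenomicRanges::findOverlaps(seg_gr, cnp_gr)
    hit_idx <- unique(S4Vectors::queryHits(hits))
    if (!length(hit_idx)) return(x)
    keep <- as.data.frame(x)[-hit_idx, , drop = FALSE]
    pieces <- lapply(hit_idx, function(i) {
      rem <- GenomicRanges::setdiff(seg_gr[i], cnp_gr)
      if (!length(rem)) return(NULL)
      df <- .gr_df(rem)
      frac <- (df$end - df$start) / (x$end[i] - x$start[i])
      data.frame(chrom = df$chrom, start = df$start, end = df$end,
                 n_probes = pmax(1, round(x$n_probes[i] * frac)),
                 log2 = x$log2[i], stringsAsFactors = FALSE)
    })
    out <- rbind(keep, do.call(rbind, pieces))
    cn_profile(sample_id(x), out, genome = attr(x, "genome"))
  } else if (inherits(x, "cn_regions") || is.data.frame(x)) {
    if (nrow(x) == 0) return(x)
    reg_gr <- .gr(x$chrom, x$start, x$end)
    drop <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(reg_gr, cnp_gr)))
    out <- x[setdiff(seq_len(nrow(x)), drop), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    stop("mask_cnp: unsupported input type")
  }
}

#' Merge unreliable small segments into their closest neighbour
#'
#' Segments supported by fewer than `min_probes` probes are unreliable on
#' SNP platforms.  Iteratively, the segment with the smallest probe count
#' below `min_probes` is absorbed into the adjacent same-chromosome segment
#' whose log2 ratio is closest: the absorbing neighbour extends its
#' coordinates over the absorbed interval, keeps its own log2, and gains
#' the absorbed probe count.  Iteration stops when no segment is below
#' `min_probes` or a chromosome is down to a single segment (a lone small
#' whole-chromosome segment is retained).  The result is a fixed point:
#' re-running the operation is the identity.
#'
#' Ties are broken deterministically: among equally small segments the
#' leftmost is processed first, and a neighbour tie in `|delta log2|`
#' absorbs leftward.
#'
#' @param profile a [cn_profile()].
#' @param min_probes integer threshold (e.g. 10 for SNP6, 5 for 500K).
#' @return merged [cn_profile()].
#' @export
merge_small_segments <- function(profile, min_probes) {
  stopifnot(inherits(profile, "cn_profile"))
  genome <- attr(profile, "genome")
  per_chrom <- lapply(split(as.data.frame(profile), profile$chrom),
                      .merge_chrom, min_probes = min_probes)
  out <- do.call(rbind, per_chrom)
  cn_profile(sample_id(profile), out, genome = genome)
}

.merge_chrom <- function(s, min_probes) {
  s <- s[order(s$start), , drop = FALSE]
  repeat {
    small <- which(s$n_probes < min_probes)
    if (!length(small) || nrow(s) == 1) return(s)
    i <- small[which.min(s$n_probes[small])]
    left <- if (i > 1) abs(s$log2[i - 1] - s$log2[i]) else Inf
    right <- if (i < nrow(s)) abs(s$log2[i + 1] - s$log2[i]) else Inf
    j <- if (left <= right) i - 1 else i + 1
    s$start[j] <- min(s$start[j], s$start[i])
    s$end[j] <- max(s$end[j], s$end[i])
    s$n_probes[j] <- s$n_probes[j] + s$n_probes[i]
    s <- s[-i, , drop = FALSE]
  }
}

#' Call per-segment aberration states
#'
#' Labels every segment `gain` / `loss` / `neutral` at the universal
#' threshold and adds the high-amplitude flags.  All inequalities are
#' strict (`log2 > 0.3` for gain, `< -0.3` for loss, `> 0.6/0.8/1.0` for
#' the gain tiers, `< -1` for homozygous deletion), so a segment at exactly
#' 0.3 is neutral.
#'
#' @param profile a [cn_profile()].
#' @param thresholds a [call_thresholds()].
#' @return data.frame: the profile's segments plus columns `state`,
#'   `gain_0.6`-style tier flags and `hd`.
#' @export
call_states <- function(profile, thresholds = call_thresholds()) {
  df <- as.data.frame(profile)
  df$state <- ifelse(df$log2 > thresholds$gain, "gain",
                     ifelse(df$log2 < thresholds$loss, "loss", "neutral"))
  for (t in thresholds$high_tiers)
    df[[sprintf("gain_%.1f", t)]] <- df$log2 > t
  df$hd <- df$log2 < thresholds$hd
  df
}
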