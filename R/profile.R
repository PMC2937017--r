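#' Copy-number profile of one sample
#'
#' A `cn_profile` holds the segmented copy-number landscape of a single
#' sample: an ordered set of non-overlapping constant-copy-number intervals,
#' each with a probe count and a log2 tumour/normal ratio.  Coordinates are
#' 0-based half-open.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `n_probes`, `log2`.
#' @param genome optional [genome_build()]; when given, chromosomes and
#'   coordinates are validated against it.
#' @return A `cn_profile` object (a data.frame with attributes `sample_id`
#'   and `genome`).
#' @export
cn_profile <- function(sample_id, segments, genome = NULL) {
  stopifnot(is.data.frame(segments))
  need <- c("chrom", "start", "end", "n_probes", "log2")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segments missing column(s): ", paste(miss, collapse = ", "))
  seg <- segments[need]
  seg$chrom <- normalize_chrom(seg$chrom)
  seg$start <- as.numeric(seg$start)
  seg$end <- as.numeric(seg$end)
  seg$n_probes <- as.numeric(seg$n_probes)
  seg$log2 <- as.numeric(seg$log2)
  chrom_levels <- if (!is.null(genome)) genome$chrom else unique(seg$chrom)
  seg <- seg[order(match(seg$chrom, chrom_levels), seg$start), ,
             drop = FALSE]
  rownames(seg) <- NULL
  structure(seg, sample_id = as.character(sample_id), genome = genome,
            class = c("cn_profile", "data.frame"))
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("cn_profile for sample ", sample_id(x), ": ", nrow(x),
      " segments on ", length(unique(x$chrom)), " chromosome(s)\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Sample identifier of a profile
#' @param x a `cn_profile`.
#' @return character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Validate a copy-number profile
#'
#' Checks the structural invariants every profile must satisfy: per
#' chromosome the segments are sorted and non-overlapping, `start < end`,
#' `n_probes >= 1`, and (when a genome is attached) chromosomes are known
#' and segments lie within chromosome bounds.
#'
#' @param x a `cn_profile`.
#' @param genome optional [genome_build()] overriding the attached one.
#' @return `x` invisibly; errors on violation.
#' @export
validate_profile <- function(x, genome = NULL) {
  stopifnot(inherits(x, "cn_profile"))
  if (is.null(genome)) genome <- attr(x, "genome")
  if (any(x$start >= x$end))
    stop("profile ", sample_id(x), ": segment with start >= end")
  if (any(x$n_probes < 1))
    stop("profile ", sample_id(x), ": segment with n_probes < 1")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown))
      stop("profile ", sample_id(x), ": unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    len <- genome$length[match(x$chrom, genome$chrom)]
    if (any(x$end > len))
      stop("profile ", sample_id(x), ": segment beyond chromosome end")
  }
  for (ch in unique(x$chrom)) {
    s <- x[x$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$start))
      stop("profile ", sample_id(x), ": segments not sorted on ", ch)
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("profile ", sample_id(x), ": overlapping segments on ", ch)
  }
  invisible(x)
}

# internal: stack a list of profiles into one data.frame with sample column
.stack_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  do.call(rbind, lapply(profiles, function(p) {
    cbind(sample = sample_id(p), as.data.frame(p),
          stringsAsFactors = FALSE)
  }))
}

# internal: GRanges of all segments of a cohort, with sample + log2 mcols
.profiles_gr <- function(profiles) {
  df <- .stack_profiles(profiles)
  .gr(df$chrom, df$start, df$end, sample = df$sample,
      n_probes = df$n_probes, log2 = df$log2)
}

# internal: split a stacked data.frame back into cn_profile objects
.unstack_profiles <- function(df, genome = NULL, sample_order = NULL) {
  if (is.null(sample_order)) sample_order <- unique(df$sample)
  out <- lapply(sample_order, function(s) {
    cn_profile(s, df[df$sample == s, , drop = FALSE], genome = genome)
  })
  names(out) <- sample_order
  out
}
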