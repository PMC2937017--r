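#' Genome build
#'
#' A genome build is the ordered set of chromosomes all coordinates in a run
#' refer to. Internally every interval in the package is 0-based half-open
#' `[start, end)` in base pairs; conversion to/from the 1-based inclusive
#' convention happens only at file boundaries (see [read_seg()]).
#'
#' @param chroms character vector of chromosome names (unique, order kept).
#' @param lengths numeric vector of chromosome lengths in bp (> 0).
#' @return A `genome_build`: data.frame with columns `chrom`, `length`.
#' @examples
#' gb <- genome_build(c("chr1", "chr2"), c(2e8, 1.5e8))
#' @export
genome_build <- function(chroms, lengths) {
  chroms <- normalize_chrom(as.character(chroms))
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths differ in length")
  if (anyDuplicated(chroms))
    stop("duplicate chromosome names: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be strictly positive")
  out <- data.frame(chrom = chroms, length = lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Default synthetic genome build
#'
#' A compact genome used by the simulator and examples: `n_chrom`
#' chromosomes named `chr1..chrN`.  Lengths default to a decreasing ladder
#' (200, 180, ... Mb) loosely echoing real karyotype scale while keeping
#' simulations cheap.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths optional explicit lengths (bp), recycled to `n_chrom`.
#' @return A [genome_build()].
#' @export
synthetic_genome <- function(n_chrom = 6, lengths = NULL) {
  if (is.null(lengths))
    lengths <- (200 - 20 * (seq_len(n_chrom) - 1)) * 1e6
  genome_build(paste0("chr", seq_len(n_chrom)),
               rep_len(lengths, n_chrom))
}

#' Normalize chromosome names to the canonical "chr"-prefixed form
#'
#' "1" -> "chr1", "X" -> "chrX", "chr1" -> "chr1", "23" -> "chrX",
#' "24" -> "chrY" (Affymetrix numeric coding).
#'
#' @param x character vector of chromosome names.
#' @return canonical names.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  if (length(x) == 0) return(character())
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "25"] <- "MT"
  paste0("chr", x)
}

# internal: GRanges from 0-based half-open columns
.gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    ...)
}

# internal: back to 0-based half-open data.frame columns
.gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
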