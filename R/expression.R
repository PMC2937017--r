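#' Gene-level copy number from a segmented profile
#'
#' The log2 copy number of a gene is the length-weighted mean of the
#' overlapping segments' log2 ratios; genes with no covering segment get
#' `NA`.
#'
#' @param profile a [cn_profile()].
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @return named numeric vector, one value per gene.
#' @export
gene_level_cn <- function(profile, genes) {
  gene_cn_matrix(list(profile), genes)[, 1]
}

#' Gene-by-sample copy-number matrix
#' @param profiles list of [cn_profile()].
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @return genes x samples matrix of length-weighted mean log2 values.
#' @export
gene_cn_matrix <- function(profiles, genes) {
  samples <- vapply(profiles, sample_id, character(1))
  gene_gr <- .gr(normalize_chrom(genes$chrom), genes$start, genes$end)
  out <- matrix(NA_real_, nrow(genes), length(profiles),
                dimnames = list(genes$gene_id, samples))
  df <- .stack_profiles(profiles)
  seg_gr <- .gr(df$chrom, df$start, df$end)
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- GenomicRanges::width(IRanges::pintersect(gene_gr[qh],
                                                seg_gr[sh]))
  col <- match(df$sample[sh], samples)
  key <- (col - 1) * nrow(genes) + qh   # linear index into out
  num <- rowsum(w * df$log2[sh], key)
  den <- rowsum(w, key)
  out[as.integer(rownames(num))] <- num / den
  out
}

# Pearson correlation + exact t-transform p (n - 2 df) on
# pairwise-complete observations; NA when degenerate
.cor_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(c(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Four-test expression linkage of associated region pairs
#'
#' For every gene pair spanning an associated region pair (gene X in
#' region A, gene Y in region B; genes are matched to regions by overlap
#' within a `flank` of the region limits), four Pearson correlation tests
#' are computed on the samples shared by the copy-number and expression
#' matrices: (a) CN of X vs CN of Y, (b) CN vs expression of X, (c) CN vs
#' expression of Y, (d) expression of X vs expression of Y.  A gene pair
#' passes when all four two-sided p-values are below `alpha` -- a screen,
#' not a corrected inference.  Pairs with fewer than 3 complete samples or
#' a zero-variance vector are flagged untestable, not failed.
#'
#' @param cn genes x samples copy-number matrix ([gene_cn_matrix()]).
#' @param expr genes x samples expression matrix.
#' @param region_pairs data.frame `a`, `b` of region labels (e.g. the
#'   selected rows of [pair_associations()]).
#' @param regions [cn_regions()] the labels refer to.
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param alpha per-test significance level (default 0.05).
#' @param flank bp added around each region when assigning genes
#'   (default 10 kb).
#' @return data.frame, one row per gene pair: regions, genes, the four
#'   `r`/`p` pairs, `min_abs_r`, `testable`, `pass`; sorted by
#'   decreasing `min_abs_r`.
#' @export
four_way_link <- function(cn, expr, region_pairs, regions, genes,
                          alpha = 0.05, flank = 1e4) {
  shared <- intersect(colnames(cn), colnames(expr))
  if (length(shared) < 3)
    stop("need at least 3 samples shared between cn and expr")
  cn <- cn[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  gene_gr <- .gr(normalize_chrom(genes$chrom),
                 pmax(0, genes$start - flank), genes$end + flank)
  reg_gr <- .gr(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(gene_gr, reg_gr)
  genes_of <- split(genes$gene_id[S4Vectors::queryHits(hits)],
                    regions$label[S4Vectors::subjectHits(hits)])
  rows <- list()
  for (k in seq_len(nrow(region_pairs))) {
    ga <- genes_of[[region_pairs$a[k]]]
    gb <- genes_of[[region_pairs$b[k]]]
    ga <- intersect(ga, intersect(rownames(cn), rownames(expr)))
    gb <- intersect(gb, intersect(rownames(cn), rownames(expr)))
    for (gx in ga) for (gy in gb) {
      t1 <- .cor_test(cn[gx, ], cn[gy, ])
      t2 <- .cor_test(cn[gx, ], expr[gx, ])
      t3 <- .cor_test(cn[gy, ], expr[gy, ])
      t4 <- .cor_test(expr[gx, ], expr[gy, ])
      rs <- c(t1["r"], t2["r"], t3["r"], t4["r"])
      ps <- c(t1["p"], t2["p"], t3["p"], t4["p"])
      testable <- !anyNA(ps)
      rows[[length(rows) + 1]] <- data.frame(
        region_a = region_pairs$a[k], region_b = region_pairs$b[k],
        gene_x = gx, gene_y = gy,
        r_cncn = rs[1], p_cncn = ps[1],
        r_cnex_x = rs[2], p_cnex_x = ps[2],
        r_cnex_y = rs[3], p_cnex_y = ps[3],
        r_exex = rs[4], p_exex = ps[4],
        min_abs_r = if (testable) min(abs(rs)) else NA_real_,
        testable = testable,
        pass = testable && all(ps < alpha),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(region_a = character(), region_b = character(),
                      gene_x = character(), gene_y = character(),
                      r_cncn = numeric(), p_cncn = numeric(),
                      r_cnex_x = numeric(), p_cnex_x = numeric(),
                      r_cnex_y = numeric(), p_cnex_y = numeric(),
                      r_exex = numeric(), p_exex = numeric(),
                      min_abs_r = numeric(), testable = logical(),
                      pass = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$min_abs_r, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
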