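#' Contingency counts for one region pair
#'
#' The 2x2 table of joint aberration status: `n11` samples aberrant at
#' both regions, `n10` at A only, `n01` at B only, `n00` at neither.
#'
#' @param n11,n10,n01,n00 non-negative cell counts.
#' @return list of class `contingency_counts` with the cells, total `n`
#'   and margins `nA = n11 + n10`, `nB = n11 + n01`.
#' @export
contingency_counts <- function(n11, n10, n01, n00) {
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  n <- n11 + n10 + n01 + n00
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n,
                 nA = n11 + n10, nB = n11 + n01),
            class = "contingency_counts")
}

#' Contingency counts from the both-aberrant count and the margins
#' @param n11 samples aberrant at both regions.
#' @param nA,nB marginal counts of aberrant samples at each region.
#' @param n cohort size.
#' @return A [contingency_counts()].
#' @export
counts_from_margins <- function(n11, nA, nB, n) {
  contingency_counts(n11, nA - n11, nB - n11, n - nA - nB + n11)
}

# vectorized signed score statistic; returns NA where margins degenerate
.signed_z <- function(n11, nA, nB, n) {
  # double arithmetic: the denominator overflows 32-bit integers
  n11 <- as.numeric(n11); nA <- as.numeric(nA)
  nB <- as.numeric(nB); n <- as.numeric(n)
  testable <- nA > 0 & nA < n & nB > 0 & nB < n
  num <- n11 * n - nA * nB
  chisq <- n * num^2 / (nA * nB * (n - nA) * (n - nB))
  z <- sign(num) * sqrt(chisq)
  z[!testable] <- NA_real_
  z
}

#' Signed score test for association of two binary aberrations
#'
#' The score test of independence in the 2x2 table from a Poisson
#' log-linear model: numerically it is the signed square root of the
#' Pearson chi-square statistic (no continuity correction), signed by the
#' direction of association (positive = co-occurrence above chance,
#' negative = mutual exclusivity), referenced to a standard normal.
#'
#' @param counts a [contingency_counts()].
#' @return list with `z`, two-sided `p`, `direction`
#'   (`"positive"`/`"negative"`/`"none"`), and `testable` (`FALSE` with
#'   `z = p = NA` when a margin is 0 or n, where the statistic is
#'   undefined; such pairs are excluded from multiplicity correction).
#' @examples
#' # 35 of 183 samples carry both gains, margins 68 and 50:
#' score_test(counts_from_margins(35, 68, 50, 183))
#' @export
score_test <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  z <- .signed_z(counts$n11, counts$nA, counts$nB, counts$n)
  if (is.na(z))
    return(list(z = NA_real_, p = NA_real_, direction = NA_character_,
                testable = FALSE))
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (z > 0) "positive" else if (z < 0) "negative" else "none"
  list(z = z, p = p, direction = direction, testable = TRUE)
}

#' Expected co-occurrence fraction under independence
#'
#' Under independence the fraction of samples aberrant at both regions is
#' the product of the marginal frequencies.
#'
#' @param freq_a,freq_b marginal aberration frequencies in `[0, 1]`.
#' @return expected both-aberrant fraction.
#' @examples
#' expected_cooccurrence(68 / 183, 50 / 183)  # ~0.10
#' expected_cooccurrence(0.37, 0.33)          # 0.12 (rounded marginals)
#' @export
expected_cooccurrence <- function(freq_a, freq_b) {
  stopifnot(all(freq_a >= 0 & freq_a <= 1), all(freq_b >= 0 & freq_b <= 1))
  freq_a * freq_b
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Explicit implementation of the BH step-up procedure: sorted p-values
#' are multiplied by `m / rank`, monotonicity is enforced from the largest
#' down, and values are capped at 1.  Selecting `q <= alpha` controls the
#' false discovery rate at `alpha` under independence/PRDS.
#'
#' @param p vector of p-values in `[0, 1]` (no NAs).
#' @return adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(!anyNA(p), all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  q[order(o)]
}

# internal: resolve/validate a pair list against the matrix columns
.resolve_pairs <- function(X, pairs) {
  if (is.null(pairs)) {
    k <- ncol(X)
    if (k < 2) stop("need at least two regions")
    idx <- utils::combn(k, 2)
    pairs <- data.frame(a = colnames(X)[idx[1, ]],
                        b = colnames(X)[idx[2, ]],
                        stringsAsFactors = FALSE)
  }
  ai <- match(pairs$a, colnames(X))
  bi <- match(pairs$b, colnames(X))
  if (anyNA(ai) || anyNA(bi))
    stop("pair list references region(s) absent from the matrix")
  list(pairs = pairs, ai = ai, bi = bi)
}

#' Score-test associations for all admissible region pairs
#'
#' Runs the signed score test on every admissible pair of columns of the
#' binary aberration matrix and applies Benjamini-Hochberg correction
#' jointly over all testable pairs (positive and negative associations in
#' one family).  Pairs with a degenerate margin (region aberrant in no or
#' all samples) are reported as untestable and excluded from the
#' correction.
#'
#' @param X binary matrix, samples x regions, unique column names.
#' @param pairs data.frame with columns `a`, `b` of region labels (e.g.
#'   from [filter_region_pairs()]); default all unordered pairs.
#' @return data.frame sorted by `q` then decreasing `|z|`: columns `a`,
#'   `b`, `n11`, `n10`, `n01`, `n00`, `z`, `p`, `q`, `direction`,
#'   `testable`.
#' @export
pair_associations <- function(X, pairs = NULL) {
  stopifnot(is.matrix(X), all(X %in% c(0, 1)))
  rp <- .resolve_pairs(X, pairs)
  n <- nrow(X)
  CP <- crossprod(X)
  cs <- colSums(X)
  n11 <- CP[cbind(rp$ai, rp$bi)]
  nA <- cs[rp$ai]
  nB <- cs[rp$bi]
  z <- .signed_z(n11, nA, nB, n)
  testable <- !is.na(z)
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_adjust(p[testable])
  out <- data.frame(a = rp$pairs$a, b = rp$pairs$b,
                    n11 = n11, n10 = nA - n11, n01 = nB - n11,
                    n00 = n - nA - nB + n11,
                    z = z, p = p, q = q,
                    direction = ifelse(is.na(z), NA_character_,
                                       ifelse(z > 0, "positive",
                                              ifelse(z < 0, "negative",
                                                     "none"))),
                    testable = testable, stringsAsFactors = FALSE)
  out <- out[order(!out$testable, out$q, -abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte Carlo column-permutation test with average-rank FDR
#'
#' For `b = 1..B` every column of `X` is permuted independently (column
#' sums, i.e. per-region aberration frequencies, are preserved) and the
#' `|z|` score of every admissible pair is recomputed.  Per pair, the
#' permutation p-value is the add-one estimator
#' `(1 + #\{b : |z_b| >= |z_obs|\}) / (B + 1)`.  The false discovery rate
#' at each observed `|z|` threshold is the average-rank (pooled-null
#' expected-exceedance) estimate: the mean number of null pair statistics
#' at or above the threshold per permutation, divided by the number of
#' observed statistics at or above it, capped at 1 and made monotone.
#'
#' @param X binary matrix, samples x regions.
#' @param pairs admissible pairs as in [pair_associations()].
#' @param B number of permutations (>= 1; default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame: `a`, `b`, observed `z`, `p` (parametric), `q`
#'   (BH), `direction`, `perm_p`, `perm_fdr`, `testable`.
#' @export
permutation_test <- function(X, pairs = NULL, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- pair_associations(X, pairs)
  rp <- .resolve_pairs(X, obs[c("a", "b")])
  n <- nrow(X)
  cs <- colSums(X)
  t_i <- which(obs$testable)
  ai <- rp$ai[t_i]; bi <- rp$bi[t_i]
  tau <- abs(obs$z[t_i])
  P <- length(t_i)
  ge <- integer(P)
  pooled <- numeric(B * P)
  for (b in seq_len(B)) {
    Xp <- apply(X, 2, sample)
    CP <- crossprod(Xp)
    zb <- abs(.signed_z(CP[cbind(ai, bi)], cs[ai], cs[bi], n))
    ge <- ge + (zb >= tau)
    pooled[((b - 1) * P + 1):(b * P)] <- zb
  }
  obs$perm_p <- NA_real_
  obs$perm_p[t_i] <- (1 + ge) / (B + 1)
  # average-rank FDR at each observed threshold
  sp <- sort(pooled)
  null_ge <- length(sp) - findInterval(tau, sp, left.open = TRUE)
  obs_ge <- length(tau) - findInterval(tau, sort(tau), left.open = TRUE)
  fdr <- pmin(1, (null_ge / B) / obs_ge)
  o <- order(tau, decreasing = TRUE)
  fdr[o] <- rev(cummin(rev(fdr[o])))
  obs$perm_fdr <- NA_real_
  obs$perm_fdr[t_i] <- fdr
  obs
}

#' Select significant pairs from an association table
#' @param assoc result of [pair_associations()] or [permutation_test()].
#' @param fdr FDR threshold (default 0.05).
#' @param method `"parametric"` (BH on the score test, the primary
#'   selector) or `"permutation"` (average-rank FDR).
#' @return the selected rows of `assoc`.
#' @export
selected_pairs <- function(assoc, fdr = 0.05,
                           method = c("parametric", "permutation")) {
  method <- match.arg(method)
  col <- if (method == "parametric") "q" else "perm_fdr"
  if (!col %in% names(assoc))
    stop("association table lacks column '", col, "'")
  keep <- !is.na(assoc[[col]]) & assoc[[col]] <= fdr
  assoc[keep, , drop = FALSE]
}

# canonical pair key (unordered)
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

#' Replication filter across two cohorts
#'
#' Keeps the pairs significant at the FDR threshold in BOTH result sets
#' with the SAME direction of association -- the test/validation design
#' that guards against cohort-specific artefacts.
#'
#' @param res_test,res_validation association tables over the same region
#'   pair universe.
#' @param fdr FDR threshold (default 0.05).
#' @param method selector, as in [selected_pairs()].
#' @return data.frame of replicated pairs: `a`, `b`, `direction`,
#'   `z_test`, `z_validation`.
#' @export
replicate_associations <- function(res_test, res_validation, fdr = 0.05,
                                   method = c("parametric",
                                              "permutation")) {
  method <- match.arg(method)
  k1 <- .pair_key(res_test$a, res_test$b)
  k2 <- .pair_key(res_validation$a, res_validation$b)
  if (!setequal(k1, k2))
    stop("mismatched region universes between test and validation")
  s1 <- selected_pairs(res_test, fdr, method)
  s2 <- selected_pairs(res_validation, fdr, method)
  key1 <- .pair_key(s1$a, s1$b)
  key2 <- .pair_key(s2$a, s2$b)
  common <- intersect(key1, key2)
  i1 <- match(common, key1)
  i2 <- match(common, key2)
  same_dir <- s1$direction[i1] == s2$direction[i2]
  out <- data.frame(a = s1$a[i1][same_dir], b = s1$b[i1][same_dir],
                    direction = s1$direction[i1][same_dir],
                    z_test = s1$z[i1][same_dir],
                    z_validation = s2$z[i2][same_dir],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Agreement between two pair selections
#'
#' @param sel_a,sel_b selections: either association tables (rows =
#'   selected pairs) or character vectors of pair keys.
#' @return list with `jaccard` (intersection over union; 1 when both
#'   empty), `frac_a` (`|A n B| / |A|`), `frac_b`, `n_common`.
#' @export
method_agreement <- function(sel_a, sel_b) {
  as_keys <- function(s) {
    if (is.data.frame(s)) .pair_key(s$a, s$b) else as.character(s)
  }
  a <- unique(as_keys(sel_a))
  b <- unique(as_keys(sel_b))
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(jaccard = if (u == 0) 1 else i / u,
       frac_a = if (length(a) == 0) 1 else i / length(a),
       frac_b = if (length(b) == 0) 1 else i / length(b),
       n_common = i)
}
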