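#' Genomic-instability measures for one sample
#'
#' Summarises the rearrangement burden of a called profile:
#' \describe{
#'   \item{n_gain / n_loss}{number of aberration events, counting maximal
#'     runs of adjacent same-state segments as one event (splitting a
#'     segment in two never changes the count).}
#'   \item{n_highgain}{gain events whose maximum log2 exceeds the first
#'     high tier (0.6) -- the number of higher-amplitude gains.}
#'   \item{n_segments}{raw segment count, a distinct measure.}
#'   \item{pct_gain / pct_loss / pct_highgain}{fraction of the covered
#'     genome at that state (high gain: length with log2 above the 0.6
#'     tier).}
#'   \item{hicks_gain / hicks_loss / hicks_total}{transition-count index
#'     of rearrangement: the number of adjacent-segment log2 steps
#'     exceeding the call threshold, upward steps (`delta > gain`),
#'     downward steps (`delta < loss`), and either.  This is this
#'     package's reading of a transition-based index; the cited original
#'     is not re-implemented.}
#' }
#'
#' @param profile a [cn_profile()].
#' @param thresholds a [call_thresholds()].
#' @return one-row data.frame with the measures above plus `sample_id`.
#' @export
instability_measures <- function(profile,
                                 thresholds = call_thresholds()) {
  st <- call_states(profile, thresholds)
  high <- thresholds$high_tiers[1]
  len <- st$end - st$start
  total <- sum(len)
  n_gain <- n_loss <- n_highgain <- 0L
  hicks_g <- hicks_l <- hicks_t <- 0L
  for (ch in unique(st$chrom)) {
    s <- st[st$chrom == ch, , drop = FALSE]
    r <- rle(s$state)
    n_gain <- n_gain + sum(r$values == "gain")
    n_loss <- n_loss + sum(r$values == "loss")
    # high gains: gain runs whose peak log2 clears the first tier
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    gi <- which(r$values == "gain")
    n_highgain <- n_highgain + sum(vapply(gi, function(i)
      max(s$log2[starts[i]:ends[i]]) > high, logical(1)))
    if (nrow(s) > 1) {
      d <- diff(s$log2)
      hicks_g <- hicks_g + sum(d > thresholds$gain)
      hicks_l <- hicks_l + sum(d < thresholds$loss)
      hicks_t <- hicks_t + sum(abs(d) > thresholds$gain)
    }
  }
  data.frame(
    sample_id = sample_id(profile),
    n_gain = n_gain, n_loss = n_loss, n_highgain = n_highgain,
    n_segments = nrow(st),
    pct_gain = sum(len[st$state == "gain"]) / total,
    pct_loss = sum(len[st$state == "loss"]) / total,
    pct_highgain = sum(len[st$log2 > high]) / total,
    hicks_gain = hicks_g, hicks_loss = hicks_l, hicks_total = hicks_t,
    stringsAsFactors = FALSE)
}

#' Instability measures for a cohort
#' @param profiles list of [cn_profile()].
#' @param thresholds a [call_thresholds()].
#' @return data.frame, one row per sample.
#' @export
instability_table <- function(profiles,
                              thresholds = call_thresholds()) {
  out <- do.call(rbind, lapply(profiles, instability_measures,
                               thresholds = thresholds))
  rownames(out) <- NULL
  out
}

#' Bin samples into quartile groups
#'
#' Groups split at the empirical 25/50/75 percentiles (type-7 quantiles);
#' values tied with a cut point go to the lower group, so the grouping is
#' invariant to input order.
#'
#' For reference, on the motivating external tumour cohort this binning
#' of per-sample segment counts produced the groups 0-18 / 19-36 /
#' 37-60 / >60; those cut points are a property of that data set, not of
#' this function, and are cited here as documentation only.
#'
#' @param values numeric vector (length >= 4, not constant).
#' @return integer group labels 1-4.
#' @export
quartile_bin <- function(values) {
  stopifnot(!anyNA(values))
  if (length(values) < 4) stop("need at least 4 samples")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  if (min(values) == max(values))
    stop("no quartile structure: constant vector")
  1L + (values > qs[1]) + (values > qs[2]) + (values > qs[3])
}

#' Four aberration groups for a region pair
#' @param X binary aberration matrix.
#' @param a,b region labels (columns of `X`).
#' @return factor with levels `neither`, `a_only`, `b_only`, `both`.
#' @export
pair_groups <- function(X, a, b) {
  xa <- X[, a]; xb <- X[, b]
  factor(ifelse(xa == 1 & xb == 1, "both",
                ifelse(xa == 1, "a_only",
                       ifelse(xb == 1, "b_only", "neither"))),
         levels = c("neither", "a_only", "b_only", "both"))
}

#' Cox proportional-hazards association of grouped covariates
#'
#' Fits a univariate Cox model per covariate (binary region status, the
#' four groups of a region pair, or quartile groups; factors with more
#' than two levels are coded categorically against their first level) and
#' reports the Wald test of the covariate, with Benjamini-Hochberg
#' correction across the supplied family.  A covariate with a group
#' lacking events is flagged (`separation = TRUE`) and gets `p = NA`,
#' excluded from the correction.
#'
#' @param covariates data.frame of covariates (factors or numeric), one
#'   row per sample, aligned with `surv`.
#' @param surv data.frame with columns `time`, `event`.
#' @param family label recorded in the output (e.g. `"regions"`,
#'   `"pairs"`, `"instability"`).
#' @return data.frame: `covariate`, `family`, `hr` (hazard ratio of the
#'   last vs first level, or per unit for numeric), `p` (Wald), `q`
#'   (BH within family), `separation`.
#' @export
survival_assoc <- function(covariates, surv, family = "covariates") {
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(surv))
  if (sum(surv$event, na.rm = TRUE) == 0) stop("no events in cohort")
  res <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    if (!is.numeric(x)) x <- factor(x)
    ok <- stats::complete.cases(x, surv$time, surv$event)
    xs <- if (is.factor(x)) droplevels(x[ok]) else x[ok]
    sep <- FALSE
    if (is.factor(xs)) {
      ev <- tapply(surv$event[ok], xs, sum)
      sep <- any(is.na(ev)) || any(ev == 0) || nlevels(xs) < 2
    }
    if (sep)
      return(data.frame(covariate = nm, family = family, hr = NA_real_,
                        p = NA_real_, separation = TRUE,
                        stringsAsFactors = FALSE))
    fit <- survival::coxph(
      survival::Surv(surv$time[ok], surv$event[ok]) ~ xs)
    wald <- fit$wald.test
    df <- length(stats::coef(fit))
    data.frame(covariate = nm, family = family,
               hr = unname(exp(stats::coef(fit)[df])),
               p = stats::pchisq(wald, df, lower.tail = FALSE),
               separation = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out
}
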