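#' Specification of one planted aberration region
#'
#' Describes how one recurrent aberration is planted in simulated tumours:
#' its locus and type, the baseline probability a tumour carries it, the
#' mixture of log2 amplitudes emitted when it does, and its loadings on
#' the latent co-occurrence factors.  Per tumour, latent factors
#' `f ~ N(0, I)` are drawn and the aberration indicator follows
#' `logit(p) = logit(base_freq) + sum(loadings * f)`, so two regions
#' loading on a shared factor with same-sign loadings co-occur and with
#' opposite signs anti-occur -- a stand-in for shared oncogenic pathways.
#'
#' @param chrom,start,end locus (0-based half-open).
#' @param aber_type `"gain"` or `"loss"`.
#' @param base_freq baseline aberration probability, in (0, 1).
#' @param amplitudes vector of log2 levels of the amplitude mixture;
#'   all positive for gains, all negative for losses.
#' @param amp_probs mixture weights (default uniform).
#' @param loadings numeric vector of latent-factor loadings (padded with
#'   zeros to the configured number of factors).
#' @param label region label.
#' @return list of class `sim_region_spec`.
#' @export
sim_region_spec <- function(chrom, start, end, aber_type, base_freq,
                            amplitudes, amp_probs = NULL,
                            loadings = numeric(), label = NULL) {
  stopifnot(base_freq > 0, base_freq < 1, start < end)
  aber_type <- match.arg(aber_type, c("gain", "loss"))
  if (aber_type == "gain" && any(amplitudes <= 0))
    stop("gain amplitudes must be positive")
  if (aber_type == "loss" && any(amplitudes >= 0))
    stop("loss amplitudes must be negative")
  if (is.null(amp_probs)) amp_probs <- rep(1, length(amplitudes))
  if (is.null(label))
    label <- sprintf("%s_%s:%.1fMb", aber_type, normalize_chrom(chrom),
                     start / 1e6)
  structure(list(chrom = normalize_chrom(chrom), start = start, end = end,
                 aber_type = aber_type, base_freq = base_freq,
                 amplitudes = amplitudes,
                 amp_probs = amp_probs / sum(amp_probs),
                 loadings = loadings, label = label),
            class = "sim_region_spec")
}

#' Simulation configuration for a synthetic tumour/normal cohort
#'
#' @param genome a [genome_build()].
#' @param n_tumours,n_normals cohort sizes (>= 0).
#' @param region_specs list of [sim_region_spec()].  Region specs that
#'   overlap on a chromosome are rejected (same `aber_type`: the planted
#'   truth would be ambiguous; any overlap: the two events cannot be
#'   emitted in one valid profile).
#' @param n_factors number of latent co-occurrence factors.
#' @param cnp_specs data.frame (`chrom`, `start`, `end`, `pop_freq`,
#'   `log2`) of inherited copy-number polymorphisms, emitted in tumours
#'   AND normals at their population frequency.
#' @param noise_sd log2 noise standard deviation applied to every emitted
#'   segment mean (default 0.1, typical of segmented SNP-array data).
#' @param probes_per_mb probe density (default 100/Mb; probe counts are
#'   `length * probes_per_mb`, floored at 1).
#' @param breakpoint_rate expected background breakpoints per Mb (default
#'   0.02), giving the passenger segmentation the merging rule consumes.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome, n_tumours, n_normals = 0,
                       region_specs = list(), n_factors = 0,
                       cnp_specs = NULL, noise_sd = 0.1,
                       probes_per_mb = 100, breakpoint_rate = 0.02,
                       seed = 1) {
  stopifnot(n_tumours >= 0, n_normals >= 0, noise_sd >= 0, n_factors >= 0)
  planted <- do.call(rbind, c(
    lapply(region_specs, function(s)
      data.frame(chrom = s$chrom, start = s$start, end = s$end,
                 type = s$aber_type, stringsAsFactors = FALSE)),
    if (!is.null(cnp_specs) && nrow(cnp_specs))
      list(data.frame(chrom = normalize_chrom(cnp_specs$chrom),
                      start = cnp_specs$start, end = cnp_specs$end,
                      type = "cnp", stringsAsFactors = FALSE))))
  if (!is.null(planted)) {
    unknown <- setdiff(unique(planted$chrom), genome$chrom)
    if (length(unknown))
      stop("planted interval on unknown chromosome: ",
           paste(unknown, collapse = ", "))
    for (ch in unique(planted$chrom)) {
      p <- planted[planted$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)])) {
        i <- which(p$start[-1] < p$end[-nrow(p)])[1]
        if (p$type[i] == p$type[i + 1] && p$type[i] != "cnp")
          stop("overlapping region specs of the same aber_type on ", ch)
        stop("overlapping planted intervals on ", ch,
             "; planted events must be disjoint per chromosome")
      }
    }
  }
  structure(list(genome = genome, n_tumours = n_tumours,
                 n_normals = n_normals, region_specs = region_specs,
                 n_factors = n_factors, cnp_specs = cnp_specs,
                 noise_sd = noise_sd, probes_per_mb = probes_per_mb,
                 breakpoint_rate = breakpoint_rate, seed = seed),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' A cohort emulating the published serous ovarian CNA landscape on a
#' compact surrogate genome: gains planted at the reported frequencies of
#' the most frequent loci (3q-like 63%, 8q-like 62%, 20q-like 47%,
#' 12p-like 39%, 19q12-like 32%), losses at X-like (46%) and 17q-like
#' (40%) loci, gain amplitude mixture over 0.4/0.7/0.9/1.2 and loss
#' mixture over -0.5/-1.3.  One latent factor couples the 19q- and
#' 20q-like gains (the replicated co-occurrence) and also loads on the
#' X-like loss; a second factor opposes the 8q-like gain and 17q-like
#' loss, planting a negative association.  Two CNP intervals are present
#' in tumours and normals at population frequencies 0.15 and 0.25.
#'
#' @param n_tumours,n_normals cohort sizes.
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n_tumours = 200, n_normals = 50,
                               seed = 1) {
  genome <- genome_build(
    c("chr3", "chr8", "chr12", "chr17", "chr19", "chr20", "chrX"),
    c(199e6, 146e6, 132e6, 79e6, 64e6, 62e6, 155e6))
  gain_amp <- c(0.4, 0.7, 0.9, 1.2)
  gain_pr <- c(0.45, 0.3, 0.15, 0.1)
  loss_amp <- c(-0.5, -1.3)
  loss_pr <- c(0.85, 0.15)
  specs <- list(
    sim_region_spec("chr3", 160e6, 185e6, "gain", 0.63, gain_amp,
                    gain_pr, label = "gain_3q26"),
    sim_region_spec("chr8", 115e6, 135e6, "gain", 0.62, gain_amp,
                    gain_pr, label = "gain_8q24",
                    loadings = c(0, -1.6)),
    sim_region_spec("chr12", 2e6, 16e6, "gain", 0.39, gain_amp, gain_pr,
                    label = "gain_12p"),
    sim_region_spec("chr19", 34e6, 36e6, "gain", 0.32, gain_amp,
                    gain_pr, loadings = c(2.2, 0),
                    label = "gain_19q12"),
    sim_region_spec("chr20", 29e6, 35e6, "gain", 0.47, gain_amp,
                    gain_pr, loadings = c(2.2, 0),
                    label = "gain_20q11"),
    sim_region_spec("chr17", 25e6, 37e6, "loss", 0.40, loss_amp,
                    loss_pr, loadings = c(0, 1.6), label = "loss_17q12"),
    sim_region_spec("chrX", 130e6, 154e6, "loss", 0.46, loss_amp,
                    loss_pr, loadings = c(1.2, 0), label = "loss_Xq"))
  cnps <- data.frame(chrom = c("chr8", "chr17"),
                     start = c(10e6, 60e6), end = c(11e6, 61.5e6),
                     pop_freq = c(0.25, 0.15), log2 = c(0.5, -0.55),
                     stringsAsFactors = FALSE)
  sim_config(genome, n_tumours, n_normals, specs, n_factors = 2,
             cnp_specs = cnps, seed = seed)
}

# intercept a such that E_f plogis(a + s*f) = f0 for f ~ N(0,1): keeps a
# region's marginal frequency at base_freq regardless of factor loadings
.calibrated_intercept <- function(f0, s) {
  if (s == 0) return(stats::qlogis(f0))
  stats::uniroot(function(a)
    stats::integrate(function(z) stats::plogis(a + s * z) *
                       stats::dnorm(z), -8, 8)$value - f0,
    c(-30, 30))$root
}

# emit one profile: planted events (chrom,start,end,log2) + background
.emit_profile <- function(sid, genome, events, noise_sd, probes_per_mb,
                          breakpoint_rate) {
  ch_out <- character(); st_out <- en_out <- lg_out <- numeric()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    len <- genome$length[ci]
    sel <- which(events$chrom == ch)
    o <- sel[order(events$start[sel])]
    ev_s <- events$start[o]; ev_e <- events$end[o]
    ev_l <- events$log2[o]
    gap_s <- c(0, ev_e); gap_e <- c(ev_s, len)
    st <- en <- numeric()
    for (bi in seq_along(gap_s)) {
      a <- gap_s[bi]; b <- gap_e[bi]
      if (a >= b) next
      k <- stats::rpois(1, (b - a) / 1e6 * breakpoint_rate)
      cuts <- if (k > 0 && b - a > 2)
        sort(unique(round(stats::runif(k, a + 1, b - 1))))
      else numeric()
      st <- c(st, a, cuts)
      en <- c(en, cuts, b)
    }
    lg <- stats::rnorm(length(st), 0, noise_sd)
    st <- c(st, ev_s); en <- c(en, ev_e); lg <- c(lg, ev_l)
    o2 <- order(st)
    st <- st[o2]; en <- en[o2]; lg <- lg[o2]
    # fuse adjacent segments with identical log2 (collapses to one
    # whole-chromosome segment when noise_sd = 0 and nothing planted)
    if (length(st) > 1) {
      idx <- which(c(TRUE, lg[-1] != lg[-length(lg)]))
      en <- en[c(idx[-1] - 1, length(en))]
      st <- st[idx]; lg <- lg[idx]
    }
    ch_out <- c(ch_out, rep(ch, length(st)))
    st_out <- c(st_out, st); en_out <- c(en_out, en)
    lg_out <- c(lg_out, lg)
  }
  np <- pmax(1, round((en_out - st_out) / 1e6 * probes_per_mb))
  cn_profile(sid, data.frame(chrom = ch_out, start = st_out,
                             end = en_out, n_probes = np, log2 = lg_out,
                             stringsAsFactors = FALSE),
             genome = genome)
}

#' Simulate a tumour/normal copy-number cohort
#'
#' Draws, per tumour, latent factors and planted region indicators from
#' the logistic model described in [sim_region_spec()]; aberrant regions
#' emit a segment at an amplitude drawn from the region's mixture plus
#' `N(0, noise_sd)` noise; CNPs are emitted in tumours and normals at
#' their population frequency; the background genome is split at
#' Poisson-distributed breakpoints into near-zero segments.  Every emitted
#' profile is validated (sorted, non-overlapping).  Fully reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `tumours` and `normals` (lists of [cn_profile()]),
#'   `truth` (binary tumours x regions matrix of planted indicators),
#'   `regions` (the planted loci as a [cn_regions()] table) and `factors`
#'   (tumours x factors matrix of latent draws).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specs <- config$region_specs
  nr <- length(specs)
  labels <- vapply(specs, `[[`, character(1), "label")
  t_ids <- sprintf("T%03d", seq_len(config$n_tumours))
  n_ids <- sprintf("N%03d", seq_len(config$n_normals))
  truth <- matrix(0L, config$n_tumours, nr,
                  dimnames = list(t_ids, labels))
  factors <- matrix(stats::rnorm(config$n_tumours * config$n_factors),
                    config$n_tumours, config$n_factors,
                    dimnames = list(t_ids, NULL))
  cnps <- config$cnp_specs
  draw_cnps <- function() {
    if (is.null(cnps) || nrow(cnps) == 0) return(NULL)
    on <- stats::runif(nrow(cnps)) < cnps$pop_freq
    if (!any(on)) return(NULL)
    data.frame(chrom = normalize_chrom(cnps$chrom[on]),
               start = cnps$start[on], end = cnps$end[on],
               log2 = cnps$log2[on] +
                 stats::rnorm(sum(on), 0, config$noise_sd),
               stringsAsFactors = FALSE)
  }
  intercepts <- vapply(specs, function(s)
    .calibrated_intercept(s$base_freq,
                          sqrt(sum(s$loadings^2))), numeric(1))
  tumours <- vector("list", config$n_tumours)
  for (t in seq_len(config$n_tumours)) {
    events <- NULL
    for (i in seq_len(nr)) {
      s <- specs[[i]]
      eta <- intercepts[i]
      if (config$n_factors > 0 && length(s$loadings))
        eta <- eta + sum(s$loadings *
                           factors[t, seq_along(s$loadings)])
      if (stats::runif(1) < stats::plogis(eta)) {
        truth[t, i] <- 1L
        amp <- sample(s$amplitudes, 1, prob = s$amp_probs) +
          stats::rnorm(1, 0, config$noise_sd)
        events <- rbind(events, data.frame(
          chrom = s$chrom, start = s$start, end = s$end, log2 = amp,
          stringsAsFactors = FALSE))
      }
    }
    events <- rbind(events, draw_cnps())
    if (is.null(events))
      events <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), log2 = numeric())
    tumours[[t]] <- .emit_profile(t_ids[t], config$genome, events,
                                  config$noise_sd, config$probes_per_mb,
                                  config$breakpoint_rate)
  }
  names(tumours) <- t_ids
  normals <- vector("list", config$n_normals)
  for (u in seq_len(config$n_normals)) {
    events <- draw_cnps()
    if (is.null(events))
      events <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), log2 = numeric())
    normals[[u]] <- .emit_profile(n_ids[u], config$genome, events,
                                  config$noise_sd, config$probes_per_mb,
                                  config$breakpoint_rate)
  }
  names(normals) <- n_ids
  lapply(tumours, validate_profile)
  lapply(normals, validate_profile)
  regions <- if (nr) cn_regions(
    vapply(specs, `[[`, character(1), "chrom"),
    vapply(specs, `[[`, numeric(1), "start"),
    vapply(specs, `[[`, numeric(1), "end"),
    labels, vapply(specs, `[[`, character(1), "aber_type"),
    provenance = "external_peak", genome = config$genome)
  else cn_regions(character(), numeric(), numeric(), character(),
                  character())
  list(tumours = tumours, normals = normals, truth = truth,
       regions = regions, factors = factors)
}

# joint P(both) for given marginals and odds ratio (minus root of the
# quadratic from the 2x2 odds-ratio identity)
.joint_from_or <- function(pa, pb, or) {
  stopifnot(or > 0)
  if (abs(or - 1) < 1e-12) return(pa * pb)
  s <- 1 + (pa + pb) * (or - 1)
  (s - sqrt(s^2 - 4 * or * (or - 1) * pa * pb)) / (2 * (or - 1))
}

#' Simulate a binary aberration matrix with planted pair associations
#'
#' Matrix-level generator for testing the association machinery directly:
#' `n_planted_pairs` column pairs are drawn from a bivariate Bernoulli
#' with marginal frequencies drawn from `freq_range` and an odds ratio
#' drawn from `or_range` (positive associations; use odds ratios < 1 for
#' exclusivity); remaining columns are independent Bernoulli draws.
#'
#' @param n_samples rows.
#' @param n_regions columns (>= 2 * n_planted_pairs); named `R1..Rk`.
#' @param n_planted_pairs number of associated pairs, planted on columns
#'   (1,2), (3,4), ...
#' @param or_range range odds ratios are drawn from (uniform).
#' @param freq_range range of marginal aberration frequencies.
#' @param seed optional RNG seed.
#' @return list: `X` (binary matrix), `planted` (data.frame `a`, `b`,
#'   `or`, `freq_a`, `freq_b`).
#' @export
simulate_matrix <- function(n_samples, n_regions, n_planted_pairs = 0,
                            or_range = c(3, 5),
                            freq_range = c(0.15, 0.4), seed = NULL) {
  stopifnot(n_regions >= 2 * n_planted_pairs)
  if (!is.null(seed)) set.seed(seed)
  freqs <- stats::runif(n_regions, freq_range[1], freq_range[2])
  X <- matrix(0L, n_samples, n_regions,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              paste0("R", seq_len(n_regions))))
  planted <- NULL
  for (j in seq_len(n_planted_pairs)) {
    a <- 2 * j - 1; b <- 2 * j
    or <- stats::runif(1, or_range[1], or_range[2])
    p11 <- .joint_from_or(freqs[a], freqs[b], or)
    probs <- c(p11, freqs[a] - p11, freqs[b] - p11,
               1 - freqs[a] - freqs[b] + p11)
    cell <- sample(4, n_samples, replace = TRUE, prob = probs)
    X[, a] <- as.integer(cell %in% c(1, 2))
    X[, b] <- as.integer(cell %in% c(1, 3))
    planted <- rbind(planted, data.frame(
      a = colnames(X)[a], b = colnames(X)[b], or = or,
      freq_a = freqs[a], freq_b = freqs[b], stringsAsFactors = FALSE))
  }
  free <- setdiff(seq_len(n_regions), seq_len(2 * n_planted_pairs))
  for (j in free)
    X[, j] <- as.integer(stats::runif(n_samples) < freqs[j])
  list(X = X, planted = planted)
}

#' Simulate expression coupled to gene copy number
#'
#' Genes assigned to a region get expression
#' `coupling * gene_level_cn + N(0, 1)`; background genes (region `NA` or
#' `"background"`) are pure standard-normal noise.
#'
#' @param tumours list of [cn_profile()].
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `region`
#'   (region label, `"background"` or `NA`).
#' @param regions [cn_regions()] the `region` column must refer to.
#' @param coupling copy-number/expression coupling (>= 0).
#' @param seed optional RNG seed.
#' @return genes x samples expression matrix.
#' @export
simulate_expression <- function(tumours, genes, regions, coupling = 1,
                                seed = NULL) {
  stopifnot(coupling >= 0)
  if (!is.null(seed)) set.seed(seed)
  assigned <- !is.na(genes$region) & genes$region != "background"
  unknown <- setdiff(genes$region[assigned], regions$label)
  if (length(unknown))
    stop("gene mapped to unknown region: ",
         paste(unknown, collapse = ", "))
  cn <- gene_cn_matrix(tumours, genes)
  noise <- matrix(stats::rnorm(length(cn)), nrow(cn), ncol(cn))
  expr <- noise
  expr[assigned, ] <- coupling * cn[assigned, , drop = FALSE] +
    noise[assigned, , drop = FALSE]
  dimnames(expr) <- dimnames(cn)
  expr
}

#' Simulate survival records with a planted proportional hazard
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(log_hr * covariate)`; censoring times are
#' independent `Uniform(0, censor_max)` (`censor_max = NULL` disables
#' censoring).
#'
#' @param covariate numeric covariate vector (one entry per sample).
#' @param log_hr log hazard ratio per unit covariate.
#' @param baseline_rate exponential baseline rate (> 0), per time unit.
#' @param censor_max upper bound of uniform censoring, or `NULL`.
#' @param seed optional RNG seed.
#' @return data.frame `time`, `event` (1 = event observed).
#' @export
simulate_survival <- function(covariate, log_hr = 0, baseline_rate = 0.2,
                              censor_max = 12, seed = NULL) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(covariate)
  t_event <- stats::rexp(n, baseline_rate * exp(log_hr * covariate))
  if (is.null(censor_max)) {
    data.frame(time = t_event, event = 1L)
  } else {
    t_cens <- stats::runif(n, 0, censor_max)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  }
}
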