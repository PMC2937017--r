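#' Pipeline configuration
#'
#' Assembles the configuration consumed by [run_stage()].  Defaults equal
#' the published analysis settings: universal call threshold of +/-0.3
#' log2, high-gain tiers 0.6/0.8/1.0, homozygous-deletion threshold -1,
#' CNP population-frequency cutoff 5%, association FDR 5%, and 1000
#' permutations.
#'
#' @param out_dir directory all stage artifacts are written to.
#' @param seed master RNG seed; stage-specific seeds are derived from it.
#' @param fdr association FDR threshold.
#' @param permutations Monte Carlo permutation count `B`.
#' @param n_tumours,n_normals synthetic cohort sizes for the `simulate`
#'   stage.
#' @param min_probes merging threshold for small segments.
#' @param cnp_freq_threshold normal-population frequency above which an
#'   interval is a CNP.
#' @param expression_coupling copy-number/expression coupling of the
#'   simulated expression data.
#' @param survival_log_hr log hazard ratio per planted aberration used
#'   when simulating outcome.
#' @param ... further entries stored verbatim.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "cnassoc_out", seed = 1,
                            fdr = 0.05, permutations = 1000,
                            n_tumours = 200, n_normals = 50,
                            min_probes = 10, cnp_freq_threshold = 0.05,
                            expression_coupling = 1,
                            survival_log_hr = 0.15, ...) {
  structure(list(out_dir = out_dir, seed = seed, fdr = fdr,
                 permutations = permutations, n_tumours = n_tumours,
                 n_normals = n_normals, min_probes = min_probes,
                 cnp_freq_threshold = cnp_freq_threshold,
                 expression_coupling = expression_coupling,
                 survival_log_hr = survival_log_hr, ...),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#' @param path JSON file of configuration entries.
#' @return A [pipeline_config()] with the file's entries overriding the
#'   defaults.
#' @export
load_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, vals)
  cfg
}

# short hash of the serialized config (analysis-relevant fields only;
# out_dir is a location, not a setting), for output provenance
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stamp <- function(config) {
  sprintf("cnassoc config=%s seed=%d", .config_hash(config),
          as.integer(config$seed))
}

.need <- function(config, files, stage) {
  paths <- file.path(config$out_dir, files)
  miss <- !file.exists(paths)
  if (any(miss))
    stop("missing artifact ", paste(files[miss], collapse = ", "),
         ": run stage '", stage, "' first")
  invisible(paths)
}

#' Run one pipeline stage
#'
#' The stages wire the package into the end-to-end workflow; they
#' communicate exclusively through files under `config$out_dir`, so any
#' stage can be re-run in isolation.  Every output file carries a header
#' comment with the configuration hash and seed.
#'
#' Stages: `simulate` (synthetic cohort, truth, expression, outcome) ->
#' `preprocess` (CNP derivation/masking + small-segment merging) ->
#' `regions` (tiered frequency regions) -> `matrix` (binary aberration
#' matrix) -> `assoc` (score test + BH) -> `perm` (permutation test) ->
#' `replicate` (test/validation split) -> `explink` (expression linkage)
#' -> `instability` -> `survival` -> `report`.
#'
#' @param stage stage name (see above).
#' @param config a [pipeline_config()].
#' @return invisibly, the paths written.
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  stage <- match.arg(stage, c("simulate", "preprocess", "regions",
                              "matrix", "assoc", "perm", "replicate",
                              "explink", "instability", "survival",
                              "report"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  stamp <- .stamp(config)
  thr <- call_thresholds()
  written <- switch(stage,
    simulate = {
      sc <- default_sim_config(config$n_tumours, config$n_normals,
                               seed = config$seed)
      sim <- simulate_cohort(sc)
      write_seg(sim$tumours, od("tumours.seg"), comment = stamp)
      write_seg(sim$normals, od("normals.seg"), comment = stamp)
      write_matrix_tsv(sim$truth, od("truth.tsv"), comment = stamp)
      write_regions(sim$regions, od("planted_regions.bed"),
                    comment = stamp)
      # genes inside each planted region + background genes
      genes <- .synthetic_genes(sim$regions, sc$genome,
                                seed = config$seed + 11)
      .write_tsv(genes, od("genes.tsv"), comment = stamp)
      expr <- simulate_expression(sim$tumours, genes, sim$regions,
                                  coupling = config$expression_coupling,
                                  seed = config$seed + 12)
      write_matrix_tsv(expr, od("expression.tsv"), row_label = "gene_id",
                       comment = stamp)
      burden <- rowSums(sim$truth)
      os <- simulate_survival(burden, log_hr = config$survival_log_hr,
                              seed = config$seed + 13)
      pfs <- simulate_survival(burden, log_hr = config$survival_log_hr,
                               seed = config$seed + 14)
      ann <- data.frame(
        sample_id = rownames(sim$truth),
        cohort = rep_len(c("test", "validation"), nrow(sim$truth)),
        subtype = "serous", grade = 3L, stage = "III",
        os_time = round(os$time * 365), os_event = os$event,
        pfs_time = round(pfs$time * 365), pfs_event = pfs$event,
        stringsAsFactors = FALSE)
      write_annotations(ann, od("annotations.tsv"), comment = stamp)
      c("tumours.seg", "normals.seg", "truth.tsv", "annotations.tsv",
        "planted_regions.bed", "genes.tsv", "expression.tsv")
    },
    preprocess = {
      .need(config, c("tumours.seg", "normals.seg"), "simulate")
      tum <- read_seg(od("tumours.seg"))
      nor <- read_seg(od("normals.seg"))
      cnp <- derive_cnp_intervals(nor, config$cnp_freq_threshold,
                                  call = thr$gain)
      write_regions(cnp, od("cnp.bed"), comment = stamp)
      clean <- lapply(tum, function(p)
        merge_small_segments(mask_cnp(p, cnp), config$min_probes))
      write_seg(clean, od("tumours_clean.seg"), comment = stamp)
      c("cnp.bed", "tumours_clean.seg")
    },
    regions = {
      .need(config, "tumours_clean.seg", "preprocess")
      tum <- read_seg(od("tumours_clean.seg"))
      rules <- default_tier_rules()
      tracks <- lapply(seq_len(nrow(rules)), function(i)
        frequency_track(tum, rules$direction[i], rules$amplitude[i]))
      regs <- tier_regions(tracks, rules)
      write_regions(regs, od("regions.bed"), comment = stamp)
      # every tier region doubles as a broad-region candidate: a pair of
      # nested same-locus tier regions is then always contained in its
      # widest member and excluded from association testing
      broad <- regs
      broad$provenance <- "broad"
      broad$label <- paste0("broad_", broad$label)
      write_regions(broad, od("broad.bed"), comment = stamp)
      c("regions.bed", "broad.bed")
    },
    matrix = {
      .need(config, c("tumours_clean.seg", "regions.bed"), "regions")
      tum <- read_seg(od("tumours_clean.seg"))
      regs <- read_regions(od("regions.bed"))
      X <- build_matrix(tum, regs, thr)
      write_matrix_tsv(X, od("matrix.tsv"), comment = stamp)
      "matrix.tsv"
    },
    assoc = {
      .need(config, c("matrix.tsv", "regions.bed", "broad.bed",
                      "cnp.bed"), "matrix")
      X <- read_matrix_tsv(od("matrix.tsv"))
      regs <- read_regions(od("regions.bed"))
      broad <- read_regions(od("broad.bed"))
      cnp <- read_regions(od("cnp.bed"))
      pairs <- filter_region_pairs(regs, broad_regions = broad,
                                   cnp = cnp)
      res <- pair_associations(X, pairs)
      .write_tsv(res, od("assoc.tsv"), comment = stamp)
      "assoc.tsv"
    },
    perm = {
      .need(config, c("matrix.tsv", "assoc.tsv"), "assoc")
      X <- read_matrix_tsv(od("matrix.tsv"))
      res <- .read_tsv(od("assoc.tsv"))
      perm <- permutation_test(X, res[c("a", "b")],
                               B = config$permutations,
                               seed = config$seed + 1)
      .write_tsv(perm, od("perm.tsv"), comment = stamp)
      "perm.tsv"
    },
    replicate = {
      .need(config, c("matrix.tsv", "assoc.tsv", "annotations.tsv"),
            "assoc")
      X <- read_matrix_tsv(od("matrix.tsv"))
      res <- .read_tsv(od("assoc.tsv"))
      ann <- read_annotations(od("annotations.tsv"))
      pairs <- res[c("a", "b")]
      split_ids <- split(ann$sample_id, ann$cohort)
      r1 <- pair_associations(X[split_ids$test, , drop = FALSE], pairs)
      r2 <- pair_associations(X[split_ids$validation, , drop = FALSE],
                              pairs)
      rep <- replicate_associations(r1, r2, fdr = config$fdr)
      .write_tsv(rep, od("replicated.tsv"), comment = stamp)
      "replicated.tsv"
    },
    explink = {
      .need(config, c("assoc.tsv", "tumours_clean.seg", "regions.bed",
                      "genes.tsv", "expression.tsv"), "assoc")
      res <- .read_tsv(od("assoc.tsv"))
      sel <- selected_pairs(res, fdr = config$fdr)
      tum <- read_seg(od("tumours_clean.seg"))
      regs <- read_regions(od("regions.bed"))
      genes <- .read_tsv(od("genes.tsv"))
      expr <- read_matrix_tsv(od("expression.tsv"))
      cn <- gene_cn_matrix(tum, genes)
      links <- four_way_link(cn, expr, sel, regs, genes)
      .write_tsv(links, od("links.tsv"), comment = stamp)
      "links.tsv"
    },
    instability = {
      .need(config, "tumours_clean.seg", "preprocess")
      tum <- read_seg(od("tumours_clean.seg"))
      inst <- instability_table(tum, thr)
      .write_tsv(inst, od("instability.tsv"), comment = stamp)
      "instability.tsv"
    },
    survival = {
      .need(config, c("matrix.tsv", "instability.tsv",
                      "annotations.tsv"), "instability")
      X <- read_matrix_tsv(od("matrix.tsv"))
      inst <- .read_tsv(od("instability.tsv"))
      ann <- read_annotations(od("annotations.tsv"))
      ann <- ann[match(rownames(X), ann$sample_id), ]
      inst <- inst[match(rownames(X), inst$sample_id), ]
      measures <- setdiff(names(inst), "sample_id")
      quart <- as.data.frame(lapply(inst[measures], function(v)
        tryCatch(factor(quartile_bin(v)), error = function(e) NULL)))
      out <- NULL
      for (ep in c("os", "pfs")) {
        surv <- data.frame(time = ann[[paste0(ep, "_time")]],
                           event = ann[[paste0(ep, "_event")]])
        sr <- survival_assoc(as.data.frame(X), surv, family = "regions")
        si <- survival_assoc(quart, surv, family = "instability")
        res <- rbind(sr, si)
        res$endpoint <- ep
        out <- rbind(out, res)
      }
      .write_tsv(out, od("survival.tsv"), comment = stamp)
      "survival.tsv"
    },
    report = {
      .need(config, c("assoc.tsv", "perm.tsv", "replicated.tsv",
                      "survival.tsv"), "survival")
      res <- .read_tsv(od("assoc.tsv"))
      perm <- .read_tsv(od("perm.tsv"))
      rep <- .read_tsv(od("replicated.tsv"))
      surv <- .read_tsv(od("survival.tsv"))
      agree <- method_agreement(selected_pairs(res, config$fdr),
                                selected_pairs(perm, config$fdr,
                                               "permutation"))
      lines <- c(
        paste0("# ", stamp),
        sprintf("testable pairs: %d", sum(res$testable)),
        sprintf("parametric selections at FDR %.2f: %d", config$fdr,
                nrow(selected_pairs(res, config$fdr))),
        sprintf("permutation selections at FDR %.2f: %d", config$fdr,
                nrow(selected_pairs(perm, config$fdr, "permutation"))),
        sprintf("method agreement (intersection/union): %.3f",
                agree$jaccard),
        sprintf("replicated pairs: %d", nrow(rep)),
        if (nrow(rep))
          sprintf("  %s -- %s (%s)", rep$a, rep$b, rep$direction),
        sprintf("survival associations with q <= 0.1: %d",
                sum(surv$q <= 0.1, na.rm = TRUE)))
      writeLines(lines, od("report.txt"))
      "report.txt"
    })
  invisible(file.path(config$out_dir, written))
}

#' Run a sequence of pipeline stages
#' @param config a [pipeline_config()].
#' @param stages stage names in order (default: the full pipeline).
#' @return invisibly, all written paths.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess", "regions",
                                    "matrix", "assoc", "perm",
                                    "replicate", "explink",
                                    "instability", "survival",
                                    "report")) {
  invisible(unlist(lapply(stages, run_stage, config = config)))
}

# synthetic gene model: a few genes tiling each planted region plus
# background genes on each chromosome
.synthetic_genes <- function(regions, genome, per_region = 3,
                             n_background = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    w <- (regions$end[i] - regions$start[i]) / per_region
    for (g in seq_len(per_region)) {
      s <- regions$start[i] + (g - 1) * w
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("%s_g%d", regions$label[i], g),
        chrom = regions$chrom[i], start = round(s),
        end = round(s + 0.5 * w), region = regions$label[i],
        stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(n_background)) {
    ci <- sample(nrow(genome), 1)
    s <- stats::runif(1, 0, genome$length[ci] - 1e5)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = sprintf("bg_g%d", b), chrom = genome$chrom[ci],
      start = round(s), end = round(s + 5e4), region = "background",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
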