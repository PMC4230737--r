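## End-to-end orchestration of the two analyses (shared aberrations:
## pooled iPSC vs ESC; factor-specific: Y-iPSC vs T-iPSC), with a
## provenance log and a checksum manifest.

#' Pipeline configuration
#'
#' @param beta,samples,annotation File paths to the beta matrix, sample
#'   sheet and probe annotation TSVs.
#' @param peaks Named character vector of BED paths, one per
#'   transcription factor (may be empty to skip enrichment).
#' @param out_dir Output directory (created if needed).
#' @param theta_diff Delta-beta significance threshold (default 0.2).
#' @param alpha FDR threshold (default 0.05).
#' @param theta_hyper,theta_hypo State-calling thresholds (defaults
#'   0.7 / 0.3).
#' @param B Number of permutations (default 10000).
#' @param w Promoter half-window in bp (default 5000).
#' @param seed Integer RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta, samples, annotation,
                            peaks = character(0), out_dir,
                            theta_diff = 0.2, alpha = 0.05,
                            theta_hyper = 0.7, theta_hypo = 0.3,
                            B = 10000, w = 5000, seed = 1) {
  stopifnot(theta_diff > 0, theta_diff < 1, alpha > 0, alpha < 1,
            theta_hypo < theta_hyper, B >= 1)
  structure(list(beta = beta, samples = samples, annotation = annotation,
                 peaks = peaks, out_dir = out_dir,
                 theta_diff = theta_diff, alpha = alpha,
                 theta_hyper = theta_hyper, theta_hypo = theta_hypo,
                 B = as.integer(B), w = as.integer(w),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full aberration-analysis pipeline
#'
#' Reads the inputs, calls differential methylation for pooled-iPSC vs
#' ESC and Y vs T, classifies shared and factor-specific aberrations,
#' summarises class composition and observed/expected ratios, runs
#' permutation enrichment at every supplied peak set (gene level, with
#' the promoter-hit table), island-context enrichment and the TSS
#' profile, and writes everything as TSV under `out_dir` together with a
#' provenance log and a `manifest.tsv` of output checksums.
#' Deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory results (paths in `$files`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$beta, config$samples, config$annotation,
              config$peaks)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(config$out_dir, "pipeline.log")
  log_lines <- c(
    sprintf("theta_diff=%g", config$theta_diff),
    sprintf("alpha=%g", config$alpha),
    sprintf("theta_hyper=%g", config$theta_hyper),
    sprintf("theta_hypo=%g", config$theta_hypo),
    sprintf("B=%d", config$B),
    sprintf("w=%d", config$w),
    sprintf("seed=%d", config$seed),
    sprintf("input_md5 %s %s", c(config$beta, config$samples,
                                 config$annotation, config$peaks),
            tools::md5sum(c(config$beta, config$samples,
                            config$annotation, config$peaks))))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mat <- stage("read_beta", read_beta_matrix(config$beta))
  sheet <- stage("read_samples", read_sample_sheet(config$samples))
  ann <- stage("read_annotation", read_probe_annotation(config$annotation))

  files <- character(0)
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    write_results_table(obj, path)
    files <<- c(files, path)
    path
  }

  ## --- shared aberrations: pooled iPSC vs ESC ---
  diff_shared <- stage("diffmeth_shared", call_differential(
    mat, sheet, c("Y_IPSC", "T_IPSC"), "ESC",
    theta_diff = config$theta_diff, alpha = config$alpha))
  emit(diff_shared, "diffmeth_ipsc_vs_esc.tsv")
  cls_shared <- stage("classify_shared", shared_aberrations(
    mat, sheet, diff_shared, config$theta_hyper, config$theta_hypo))
  emit(cls_shared, "classified_shared.tsv")
  emit(class_composition(cls_shared), "composition_shared.tsv")

  ## --- factor-specific aberrations: Y vs T ---
  diff_yt <- stage("diffmeth_yt", call_differential(
    mat, sheet, "Y_IPSC", "T_IPSC",
    theta_diff = config$theta_diff, alpha = config$alpha))
  emit(diff_yt, "diffmeth_y_vs_t.tsv")
  cls_factor <- stage("classify_factor", factor_specific_aberrations(
    mat, sheet, diff_yt, config$theta_hyper, config$theta_hypo))
  emit(cls_factor, "classified_factor_specific.tsv")
  for (sc in c("Y_specific", "T_specific")) {
    emit(class_composition(cls_factor[cls_factor$scope == sc, ]),
         paste0("composition_", tolower(sc), ".tsv"))
  }

  ## --- observed/expected class ratios ---
  oe <- list()
  if (any(cls_shared$class %in% ABERRATION_CLASSES)) {
    oe$shared <- stage("obs_exp_shared", observed_expected_class_ratio(
      cls_shared, mat, sheet, n_draws = config$B, seed = config$seed,
      theta_hyper = config$theta_hyper, theta_hypo = config$theta_hypo))
    emit(oe$shared, "obs_exp_ratio_shared.tsv")
  }

  ## --- enrichment at binding peaks ---
  enrich_rows <- list()
  gene_hits <- list()
  all_cls <- rbind(cls_shared, cls_factor)
  for (fac in names(config$peaks)) {
    pk <- stage(paste0("read_peaks_", fac),
                read_bed_peaks(config$peaks[[fac]], fac))
    for (sc in unique(all_cls$scope)) {
      cp <- all_cls[all_cls$scope == sc, , drop = FALSE]
      if (!any(cp$class %in% ABERRATION_CLASSES)) next
      gl <- stage(paste0("enrich_", fac, "_", sc), gene_level_enrichment(
        cp, ann, pk, w = config$w, B = config$B, seed = config$seed))
      r <- gl$result
      enrich_rows[[paste(fac, sc)]] <- data.frame(
        factor = fac, scope = sc, observed = r$observed_overlap,
        n_query = r$n_query, null_mean = r$null_mean,
        null_sd = r$null_sd, outside_null = r$outside_null,
        p_enrichment = r$p_enrichment, p_depletion = r$p_depletion,
        stringsAsFactors = FALSE)
      gene_hits[[paste(fac, sc)]] <-
        data.frame(scope = rep(sc, nrow(gl$hits)), gl$hits,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(enrich_rows)) {
    emit(do.call(rbind, c(enrich_rows, list(make.row.names = FALSE))),
         "enrichment_binding_sites.tsv")
    emit(do.call(rbind, c(gene_hits, list(make.row.names = FALSE))),
         "gene_promoter_hits.tsv")
  }

  ## --- genomic context ---
  if (any(all_cls$class %in% ABERRATION_CLASSES)) {
    emit(island_context_enrichment(all_cls, ann, B = min(config$B, 2000),
                                   seed = config$seed),
         "island_context_enrichment.tsv")
    emit(tss_distance_profile(all_cls, ann), "tss_distance_profile.tsv")
  }

  ## --- sample similarity ---
  cm <- pairwise_correlation_matrix(mat)
  emit(data.frame(sample_id = rownames(cm), cm, check.names = FALSE),
       "sample_correlation.tsv")
  cl <- cluster_samples(cm, k = 3)
  emit(data.frame(sample_id = names(cl), cluster = cl),
       "sample_clusters.tsv")
  pc <- pca_scores(mat, 2)
  emit(data.frame(sample_id = rownames(pc), pc, check.names = FALSE),
       "pca_scores.tsv")

  writeLines(log_lines, log_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_results_table(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(diff_shared = diff_shared, diff_yt = diff_yt,
                 classified_shared = cls_shared,
                 classified_factor = cls_factor,
                 obs_exp = oe, enrichment = enrich_rows,
                 correlation = cm, clusters = cl, pca = pc,
                 files = files, log = log_path))
}

#' One-command synthetic end-to-end demo
#'
#' Simulates a dataset with [generate_dataset()], writes the inputs,
#' generates one enriched peak set per reprogramming factor, and runs
#' [run_full_pipeline()] on them.
#'
#' @param out_dir Output directory.
#' @param seed Integer RNG seed.
#' @param config Optional [simulation_config()]; defaults to
#'   `simulation_config(seed = seed)`.
#' @return Invisible pipeline result list.
#' @export
run_demo <- function(out_dir, seed = 1,
                     config = simulation_config(seed = seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_dataset(config)
  beta_path <- file.path(out_dir, "beta.tsv")
  sheet_path <- file.path(out_dir, "samples.tsv")
  ann_path <- file.path(out_dir, "annotation.tsv")
  write_beta_matrix(sim$beta, beta_path)
  write_results_table(sim$sheet, sheet_path)
  write_results_table(sim$annotation, ann_path)

  factors <- c(OCT4 = 4, SOX2 = 1, NANOG = 8, KLF4 = 1, cMYC = 1)
  peak_paths <- character(0)
  for (i in seq_along(factors)) {
    fac <- names(factors)[i]
    pk <- generate_peaks(sim$truth, sim$annotation, fac,
                         enrichment_odds = factors[[i]],
                         seed = seed + i)
    p <- file.path(out_dir, paste0("peaks_", fac, ".bed"))
    write_bed_peaks(pk, p)
    peak_paths[fac] <- p
  }

  cfg <- pipeline_config(beta = beta_path, samples = sheet_path,
                         annotation = ann_path, peaks = peak_paths,
                         out_dir = file.path(out_dir, "results"),
                         seed = seed)
  run_full_pipeline(cfg)
}
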