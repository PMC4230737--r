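## Sample-level similarity structure (correlation clustering, PCA),
## RRBS-vs-array concordance, and tumour-vs-normal delta-beta profiling
## at aberrant CpGs.

#' Pairwise Pearson correlation of samples
#'
#' Pairwise-complete over non-missing probes; symmetric with unit
#' diagonal.
#'
#' @param matrix Beta matrix (probes x samples).
#' @return Sample x sample correlation matrix.
#' @export
pairwise_correlation_matrix <- function(matrix) {
  cm <- stats::cor(matrix, use = "pairwise.complete.obs",
                   method = "pearson")
  diag(cm) <- 1
  cm
}

#' Cluster samples by methylation correlation
#'
#' Average-linkage hierarchical clustering of the distance `1 - r`,
#' cut at `k` clusters — a deterministic simplification of consensus
#' clustering that recovers the same parental / iPSC / ESC structure on
#' clearly separated groups.
#'
#' @param correlation Sample correlation matrix.
#' @param k Number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cluster_samples <- function(correlation, k) {
  d <- stats::as.dist(1 - correlation)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}

#' Principal-component scores of sample methylomes
#'
#' PCA of the mean-centred probe-wise data (samples as observations).
#' Probes with any missing value are dropped before decomposition.
#' Scores are deterministic up to component sign.
#'
#' @param matrix Beta matrix.
#' @param n_components Number of components to return.
#' @return Sample x component score matrix.
#' @export
pca_scores <- function(matrix, n_components = 2) {
  complete <- stats::complete.cases(matrix)
  x <- t(matrix[complete, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  pc$x[, seq_len(n_components), drop = FALSE]
}

#' RRBS-versus-array concordance at shared CpGs
#'
#' Joins RRBS records to array probes on exact (chromosome, position),
#' keeps CpGs with at least `min_coverage` reads, computes the RRBS
#' methylation level as methylated/total, and reports the Pearson
#' correlation with the array betas. Both assays measure absolute
#' methylation, so no normalisation is applied.
#'
#' @param rrbs RRBS profile data.frame.
#' @param beta Named numeric vector of array betas for one sample
#'   (names = probe ids).
#' @param annotation Probe annotation supplying probe coordinates.
#' @param min_coverage Minimum read coverage per CpG (default 5).
#' @return List with `n_shared_cpgs`, `pearson_r` (NA when fewer than two
#'   shared CpGs), `min_coverage`.
#' @export
rrbs_array_concordance <- function(rrbs, beta, annotation,
                                   min_coverage = 5) {
  rrbs <- rrbs[rrbs$total_count >= min_coverage, , drop = FALSE]
  ann <- annotation[match(names(beta), annotation$probe_id), ]
  key_arr <- paste(ann$chrom, ann$pos)
  key_rrbs <- paste(rrbs$chrom, rrbs$pos)
  m <- match(key_arr, key_rrbs)
  ok <- !is.na(m) & !is.na(beta)
  n <- sum(ok)
  r <- if (n >= 2) {
    stats::cor(beta[ok], rrbs$meth_count[m[ok]] / rrbs$total_count[m[ok]])
  } else NA_real_
  list(n_shared_cpgs = n, pearson_r = r, min_coverage = min_coverage)
}

#' Tumour-versus-normal delta-beta profile at aberrant CpGs
#'
#' Computes the per-CpG tumour-minus-normal mean delta beta, summarises
#' it by aberration class and scope for the supplied aberrant probe
#' sets, and tests — with the shared permutation engine — whether each
#' scope's Class I (de novo methylation) probes are enriched among
#' cancer-hypermethylated CpGs (`delta > theta_diff`).
#'
#' @param tumor,normal Beta matrices over a common probe set.
#' @param classified_probes Classified aberrant probes (shared and/or
#'   factor-specific scopes).
#' @param theta_diff Delta-beta cutoff defining cancer hyper/hypo
#'   methylation (default 0.2).
#' @param B,seed Permutation count and RNG seed for the enrichment test.
#' @return List with `delta` (named per-CpG delta beta), `by_class`
#'   (mean delta per class x scope), and `class1_enrichment` (one
#'   `enrichment_result` per scope with Class I probes).
#' @export
cancer_delta_profile <- function(tumor, normal, classified_probes,
                                 theta_diff = 0.2, B = 10000, seed = 1) {
  shared_probes <- intersect(rownames(tumor), rownames(normal))
  delta <- rowMeans(tumor[shared_probes, , drop = FALSE], na.rm = TRUE) -
    rowMeans(normal[shared_probes, , drop = FALSE], na.rm = TRUE)

  cp <- classified_probes[classified_probes$probe_id %in% shared_probes &
                            classified_probes$class %in%
                              ABERRATION_CLASSES, , drop = FALSE]
  by_class <- if (nrow(cp)) {
    stats::aggregate(delta ~ class + scope,
                     data = data.frame(class = cp$class, scope = cp$scope,
                                       delta = delta[cp$probe_id]),
                     FUN = mean)
  } else {
    data.frame(class = character(0), scope = character(0),
               delta = numeric(0))
  }

  hyper_cpgs <- names(delta)[!is.na(delta) & delta > theta_diff]
  enr <- list()
  for (sc in unique(cp$scope)) {
    q <- unique(cp$probe_id[cp$scope == sc & cp$class == "CLASS_I"])
    if (length(q) == 0) next
    enr[[sc]] <- permutation_set_enrichment(
      q, shared_probes, hyper_cpgs,
      label = paste0(sc, "_CLASS_I_vs_cancer_hyper"), B = B, seed = seed)
  }
  list(delta = delta, by_class = by_class, class1_enrichment = enr)
}
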