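## Permutation-based enrichment of aberrant CpGs and genes at
## transcription-factor binding regions, plus island-context and
## TSS-distance profiling. The permutation engine draws query-sized probe
## sets uniformly without replacement from the universe (default: all
## probes on the array) and reports exact plus-one p-values, never zero.

## Logical per-probe peak-coverage indicator, in annotation row order.
## An array probe at 1-based position p overlaps a BED interval (s, e)
## iff s <= p - 1 < e, i.e. the 1-based closed interval [s + 1, e].
probe_peak_indicator <- function(annotation, peaks) {
  ok <- !is.na(annotation$chrom) & !is.na(annotation$pos)
  hit <- rep(FALSE, nrow(annotation))
  if (nrow(peaks) > 0 && any(ok)) {
    probe_gr <- GenomicRanges::GRanges(
      annotation$chrom[ok],
      IRanges::IRanges(annotation$pos[ok], width = 1))
    peak_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    hit[ok] <- GenomicRanges::countOverlaps(probe_gr, peak_gr) > 0
  }
  names(hit) <- annotation$probe_id
  attr(hit, "n_excluded") <- sum(!ok)
  hit
}

#' Count query probes overlapping a peak set
#'
#' A probe counts when its 1-based position falls inside at least one
#' 0-based half-open BED interval. Probes without coordinates are
#' excluded with a warning.
#'
#' @param query_probes Character vector of probe ids.
#' @param annotation Probe annotation providing coordinates.
#' @param peaks A `peak_set`.
#' @return Integer overlap count.
#' @export
overlap_count <- function(query_probes, annotation, peaks) {
  idx <- match(query_probes, annotation$probe_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " query probe(s) without annotation excluded")
    idx <- idx[!is.na(idx)]
  }
  hit <- probe_peak_indicator(annotation[idx, , drop = FALSE], peaks)
  if (attr(hit, "n_excluded") > 0) {
    warning(attr(hit, "n_excluded"),
            " query probe(s) without coordinates excluded")
  }
  sum(hit)
}

## Core permutation null: draw k of N indicator entries B times, without
## replacement within each draw, and return the B overlap counts.
permutation_null_counts <- function(hit, k, B, seed) {
  N <- length(hit)
  with_seed(seed, {
    vapply(seq_len(B), function(i) sum(hit[sample.int(N, k)]), integer(1))
  })
}

## Assemble an enrichment_result from an observed count and null counts.
enrichment_result <- function(factor_name, observed, null_counts, B, seed,
                              n_query) {
  p_enr <- (sum(null_counts >= observed) + 1) / (B + 1)
  p_dep <- (sum(null_counts <= observed) + 1) / (B + 1)
  structure(list(
    factor_name = factor_name,
    observed_overlap = as.integer(observed),
    n_query = as.integer(n_query),
    null_mean = mean(null_counts),
    null_sd = stats::sd(null_counts),
    null_quantiles = stats::quantile(null_counts, c(0.025, 0.975),
                                     names = TRUE),
    null_range = range(null_counts),
    outside_null = observed < min(null_counts) ||
      observed > max(null_counts),
    p_enrichment = p_enr,
    p_depletion = p_dep,
    n_permutations = as.integer(B),
    seed = as.integer(seed)), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment [%s]: observed %d of %d (null %.2f +/- %.2f)\n",
    x$factor_name, x$observed_overlap, x$n_query, x$null_mean, x$null_sd))
  cat(sprintf("  p_enrichment = %.4g, p_depletion = %.4g (B = %d)%s\n",
              x$p_enrichment, x$p_depletion, x$n_permutations,
              if (x$outside_null) " [outside null range]" else ""))
  invisible(x)
}

#' Permutation test of probe-level overlap enrichment at binding peaks
#'
#' The observed statistic is the number of query probes covered by a
#' peak. Each of the `B` permutations draws `|query|` probes uniformly
#' without replacement from the universe and recounts; exact plus-one
#' p-values are reported for both enrichment
#' (`(#{null >= obs} + 1) / (B + 1)`) and depletion (with `<=`).
#' Deterministic under a fixed seed.
#'
#' @param query_probes Probe ids of the aberrant (query) set; must be a
#'   subset of `universe_probes`.
#' @param universe_probes Probe ids of the sampling universe (default in
#'   the pipeline: all probes on the array).
#' @param annotation Probe annotation.
#' @param peaks A `peak_set`.
#' @param B Number of permutations (default 10000).
#' @param seed Integer RNG seed.
#' @return An `enrichment_result` (observed count, null summaries, exact
#'   p-values).
#' @export
permutation_enrichment <- function(query_probes, universe_probes,
                                   annotation, peaks, B = 10000,
                                   seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (length(query_probes) > length(universe_probes)) {
    stop("query set larger than universe")
  }
  if (!all(query_probes %in% universe_probes)) {
    stop("query probes must be a subset of the universe")
  }
  idx <- match(universe_probes, annotation$probe_id)
  if (any(is.na(idx))) stop("universe probes missing from annotation")
  hit <- probe_peak_indicator(annotation[idx, , drop = FALSE], peaks)
  names(hit) <- universe_probes
  observed <- sum(hit[query_probes])
  null_counts <- permutation_null_counts(hit, length(query_probes), B, seed)
  enrichment_result(attr(peaks, "factor_name"), observed, null_counts,
                    B, seed, length(query_probes))
}

#' Permutation test of overlap with an arbitrary probe set
#'
#' Same engine as [permutation_enrichment()] but the "hit" criterion is
#' membership in `hit_probes` rather than peak coverage — used, e.g., to
#' test whether iPSC Class I CpGs are enriched among tumour-
#' hypermethylated CpGs.
#'
#' @param query_probes,universe_probes Probe id vectors, query within
#'   universe.
#' @param hit_probes Probe ids counting as hits.
#' @param label Name recorded in the result.
#' @param B,seed Permutation count and RNG seed.
#' @return An `enrichment_result`.
#' @export
permutation_set_enrichment <- function(query_probes, universe_probes,
                                       hit_probes, label = "set",
                                       B = 10000, seed = 1) {
  if (length(query_probes) > length(universe_probes)) {
    stop("query set larger than universe")
  }
  if (!all(query_probes %in% universe_probes)) {
    stop("query probes must be a subset of the universe")
  }
  hit <- universe_probes %in% hit_probes
  names(hit) <- universe_probes
  observed <- sum(hit[query_probes])
  null_counts <- permutation_null_counts(hit, length(query_probes), B, seed)
  enrichment_result(label, observed, null_counts, B, seed,
                    length(query_probes))
}

#' Gene-level enrichment of aberrant promoters at binding peaks
#'
#' The unit of counting is the gene: a gene is hit when at least one
#' aberrant probe lying within `w` bp of its TSS overlaps a binding
#' interval. The permutation null redraws probe sets of the query size
#' from the universe and recounts genes, so duplicated probes in one
#' promoter never inflate the statistic.
#'
#' @param classified_probes Classified probe data.frame (named-class rows
#'   form the query); may carry a `delta_beta` column for the hit table.
#' @param annotation Probe annotation with `nearest_gene` and
#'   `tss_distance`.
#' @param peaks A `peak_set`.
#' @param w Promoter half-window around the TSS in bp (default 5000).
#' @param B,seed Permutation count and RNG seed.
#' @param universe_probes Sampling universe (default: all annotated
#'   probes).
#' @return List with `result` (an `enrichment_result` counting genes) and
#'   `hits` (data.frame gene, probe_id, tss_offset, class, factor,
#'   delta_beta).
#' @export
gene_level_enrichment <- function(classified_probes, annotation, peaks,
                                  w = 5000, B = 10000, seed = 1,
                                  universe_probes = annotation$probe_id) {
  idx <- match(universe_probes, annotation$probe_id)
  if (any(is.na(idx))) stop("universe probes missing from annotation")
  ann <- annotation[idx, , drop = FALSE]
  in_peak <- probe_peak_indicator(ann, peaks)
  promoter <- !is.na(ann$nearest_gene) & !is.na(ann$tss_distance) &
    abs(ann$tss_distance) <= w
  ## gene index per probe; 0 when the probe cannot produce a gene hit
  gene_levels <- unique(ann$nearest_gene[promoter & in_peak])
  hitgene <- ifelse(promoter & in_peak,
                    match(ann$nearest_gene, gene_levels), 0L)
  hitgene[is.na(hitgene)] <- 0L
  names(hitgene) <- universe_probes

  query <- unique(
    classified_probes$probe_id[classified_probes$class %in%
                                 ABERRATION_CLASSES])
  query <- intersect(query, universe_probes)
  count_genes <- function(idx) {
    g <- hitgene[idx]
    length(unique(g[g > 0]))
  }
  observed <- count_genes(match(query, universe_probes))
  null_counts <- with_seed(seed, {
    N <- length(universe_probes)
    k <- length(query)
    vapply(seq_len(B), function(i) count_genes(sample.int(N, k)),
           integer(1))
  })
  res <- enrichment_result(attr(peaks, "factor_name"), observed,
                           null_counts, B, seed, length(query))

  qi <- match(query, universe_probes)
  hit_q <- qi[hitgene[qi] > 0]
  hits <- data.frame(
    gene = ann$nearest_gene[hit_q],
    probe_id = universe_probes[hit_q],
    tss_offset = ann$tss_distance[hit_q],
    class = classified_probes$class[match(universe_probes[hit_q],
                                          classified_probes$probe_id)],
    factor = rep(attr(peaks, "factor_name"), length(hit_q)),
    delta_beta = if ("delta_beta" %in% names(classified_probes)) {
      classified_probes$delta_beta[match(universe_probes[hit_q],
                                         classified_probes$probe_id)]
    } else rep(NA_real_, length(hit_q)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(result = res, hits = hits[order(hits$gene), , drop = FALSE])
}

#' Island-context enrichment of aberration classes
#'
#' For each named class, compares the observed CpG-island-context
#' composition of its probes with uniform redraws of equal-size sets
#' from the universe: ratio = observed / mean(null), with a two-sided
#' plus-one empirical p per (class, context) cell. Empty classes are
#' reported with NA ratios.
#'
#' @param classified_probes Classified probe data.frame.
#' @param annotation Probe annotation with `island_context`.
#' @param universe_probes Sampling universe (default: all annotated
#'   probes).
#' @param B Number of null draws (default 2000).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `class`, `island_context`, `observed`,
#'   `expected`, `ratio`, `p_value`.
#' @export
island_context_enrichment <- function(classified_probes, annotation,
                                      universe_probes = annotation$probe_id,
                                      B = 2000, seed = 1) {
  idx <- match(universe_probes, annotation$probe_id)
  if (any(is.na(idx))) stop("universe probes missing from annotation")
  ctx <- factor(annotation$island_context[idx], levels = ISLAND_CONTEXTS)
  ctx_i <- as.integer(ctx)
  out <- list()
  seed_i <- seed
  for (cls in ABERRATION_CLASSES) {
    ids <- classified_probes$probe_id[classified_probes$class == cls]
    ids <- intersect(unique(ids), universe_probes)
    k <- length(ids)
    if (k == 0) {
      out[[cls]] <- data.frame(class = cls, island_context = ISLAND_CONTEXTS,
                               observed = 0L, expected = NA_real_,
                               ratio = NA_real_, p_value = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    obs <- tabulate(ctx_i[match(ids, universe_probes)], nbins = 4)
    null <- with_seed(seed_i, {
      vapply(seq_len(B), function(i) {
        tabulate(ctx_i[sample.int(length(ctx_i), k)], nbins = 4)
      }, integer(4))
    })
    expected <- rowMeans(null)
    p <- vapply(1:4, function(c) {
      p_hi <- (sum(null[c, ] >= obs[c]) + 1) / (B + 1)
      p_lo <- (sum(null[c, ] <= obs[c]) + 1) / (B + 1)
      min(1, 2 * min(p_hi, p_lo))
    }, numeric(1))
    out[[cls]] <- data.frame(class = cls, island_context = ISLAND_CONTEXTS,
                             observed = obs, expected = expected,
                             ratio = ifelse(expected > 0, obs / expected,
                                            NA_real_),
                             p_value = p, stringsAsFactors = FALSE)
    seed_i <- seed_i + 1
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Histogram of probe-to-TSS distances per scope
#'
#' @param classified_probes Classified probe data.frame with a `scope`
#'   column.
#' @param annotation Probe annotation with `tss_distance`.
#' @param bins Numeric vector of bin breakpoints in bp (default 5 kb bins
#'   over +/- 50 kb).
#' @return data.frame with columns `scope`, `bin_start`, `bin_end`,
#'   `count`; probes without gene annotation are excluded, so counts per
#'   scope sum to the number of gene-annotated probes.
#' @export
tss_distance_profile <- function(classified_probes, annotation,
                                 bins = seq(-50000, 50000, by = 5000)) {
  d_all <- annotation$tss_distance[match(classified_probes$probe_id,
                                         annotation$probe_id)]
  out <- list()
  for (sc in unique(classified_probes$scope)) {
    d <- d_all[classified_probes$scope == sc]
    d <- d[!is.na(d)]
    d <- pmin(pmax(d, min(bins)), max(bins))  # clamp into range
    counts <- table(cut(d, breaks = bins, right = FALSE,
                        include.lowest = TRUE))
    out[[sc]] <- data.frame(scope = sc, bin_start = utils::head(bins, -1),
                            bin_end = bins[-1], count = as.integer(counts),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
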