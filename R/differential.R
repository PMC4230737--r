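## Per-probe two-group differential methylation: delta beta, Wilcoxon
## rank-sum p, Benjamini-Hochberg FDR, and the significance rule
## |delta beta| > 0.2 AND q < 0.05 (both strict).

#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Uses the exact null distribution when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' mid-ranks, tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors of beta values in `[0, 1]`, one per group.
#' @return Two-sided p-value in (0, 1].
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  if (any(c(x, y) < 0) || any(c(x, y) > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- unname(res$p.value)
  # degenerate case: zero rank variance (e.g. all values tied) carries
  # no evidence against the null
  if (is.na(p)) p <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j`,
#' capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

## Group means with the >50%-missing rule: a probe missing in more than
## half of a group's samples gets an NA mean for that group.
group_mean_beta <- function(matrix, sheet, group) {
  ids <- samples_in_group(sheet, group)
  if (length(ids) == 0) stop("group '", group, "' has no samples")
  sub <- matrix[, ids, drop = FALSE]
  n_ok <- rowSums(!is.na(sub))
  m <- rowMeans(sub, na.rm = TRUE)
  m[n_ok == 0 | n_ok < length(ids) / 2] <- NA
  m
}

#' Call differentially methylated probes between two groups
#'
#' For each probe with at least one non-missing value in each group,
#' computes delta beta (mean of `group_a` minus mean of `group_b`), a
#' Wilcoxon rank-sum p-value, BH q-values over all tested probes
#' (array-wide), and the significance flag
#' `|delta_beta| > theta_diff AND q_fdr < alpha` (strict inequalities, so
#' a difference of exactly 0.2 is not significant).
#'
#' When either group has fewer than two samples a rank test is undefined;
#' the call then falls back to the pure `|delta_beta| > theta_diff`
#' threshold rule (p and q reported as NA) and says so via a message.
#'
#' @param matrix Beta matrix.
#' @param sheet Sample sheet.
#' @param group_a,group_b Group labels to compare (may each be a vector
#'   of labels to pool, e.g. `c("Y_IPSC", "T_IPSC")` for all iPSCs).
#' @param theta_diff Delta-beta threshold (default 0.2).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with columns `probe_id`, `delta_beta`, `p_raw`,
#'   `q_fdr`, `significant`.
#' @export
call_differential <- function(matrix, sheet, group_a, group_b,
                              theta_diff = 0.2, alpha = 0.05) {
  ids_a <- samples_in_group(sheet, group_a)
  ids_b <- samples_in_group(sheet, group_b)
  if (length(ids_a) == 0) stop("group '", paste(group_a, collapse = "+"),
                               "' absent from sample sheet")
  if (length(ids_b) == 0) stop("group '", paste(group_b, collapse = "+"),
                               "' absent from sample sheet")
  ids_a <- intersect(ids_a, colnames(matrix))
  ids_b <- intersect(ids_b, colnames(matrix))
  a <- matrix[, ids_a, drop = FALSE]
  b <- matrix[, ids_b, drop = FALSE]

  tested <- rowSums(!is.na(a)) >= 1 & rowSums(!is.na(b)) >= 1
  a <- a[tested, , drop = FALSE]
  b <- b[tested, , drop = FALSE]

  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  na_a <- rowSums(!is.na(a)) < ncol(a) / 2
  na_b <- rowSums(!is.na(b)) < ncol(b) / 2
  delta <- mean_a - mean_b
  delta[na_a | na_b] <- NA

  threshold_only <- length(ids_a) < 2 || length(ids_b) < 2
  if (threshold_only) {
    message("a group has a single sample; falling back to the ",
            "|delta beta| > ", theta_diff, " threshold rule (no rank test)")
    p <- rep(NA_real_, nrow(a))
    q <- rep(NA_real_, nrow(a))
    sig <- !is.na(delta) & abs(delta) > theta_diff
  } else {
    p <- vapply(seq_len(nrow(a)), function(i) {
      rank_sum_test(a[i, !is.na(a[i, ])], b[i, !is.na(b[i, ])])
    }, numeric(1))
    q <- bh_fdr(p)
    sig <- !is.na(delta) & abs(delta) > theta_diff & q < alpha
  }

  data.frame(probe_id = rownames(a), delta_beta = delta, p_raw = p,
             q_fdr = q, significant = sig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample fraction of probes diverging from a reference group mean
#'
#' For every sample in `group`, the fraction of probes whose beta differs
#' from the `ref_group` mean by at least `threshold` — the summary behind
#' "X% of CpGs in fibroblasts/iPSCs differ from ESCs".
#'
#' @param matrix Beta matrix.
#' @param sheet Sample sheet.
#' @param group Group whose samples are profiled.
#' @param ref_group Reference group (default ESC).
#' @param threshold Absolute delta-beta cutoff (default 0.2; this summary
#'   uses >= as in the descriptive boxplots, not the strict differential
#'   rule).
#' @return Named numeric vector, one fraction per sample in `group`.
#' @export
fraction_divergent <- function(matrix, sheet, group, ref_group = "ESC",
                               threshold = 0.2) {
  ref_mean <- group_mean_beta(matrix, sheet, ref_group)
  ids <- samples_in_group(sheet, group)
  vapply(ids, function(s) {
    d <- abs(matrix[, s] - ref_mean)
    mean(d >= threshold, na.rm = TRUE)
  }, numeric(1))
}

#' Per-sample fractions of hyper- and hypomethylated probes
#'
#' @param matrix Beta matrix.
#' @param theta_hyper,theta_hypo State-calling thresholds (strict; see
#'   [call_state()]).
#' @return data.frame with columns `sample_id`, `frac_hyper`, `frac_hypo`.
#' @export
methylation_state_summary <- function(matrix, theta_hyper = 0.7,
                                      theta_hypo = 0.3) {
  data.frame(
    sample_id = colnames(matrix),
    frac_hyper = colMeans(matrix > theta_hyper, na.rm = TRUE),
    frac_hypo = colMeans(matrix < theta_hypo, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}
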