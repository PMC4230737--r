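## Discrete methylation state calling and the four-class aberration
## taxonomy:
##   Class I   de novo methylation      (FIB hypo,  ESC hypo,  iPSC hyper)
##   Class II  failed methylation       (FIB hypo,  ESC hyper, iPSC hypo)
##   Class III failed demethylation     (FIB hyper, ESC hypo,  iPSC hyper)
##   Class IV  de novo demethylation    (FIB hyper, ESC hyper, iPSC hypo)

ABERRATION_CLASSES <- c("CLASS_I", "CLASS_II", "CLASS_III", "CLASS_IV")

#' Call a discrete methylation state from a (group mean) beta value
#'
#' HYPER when beta > `theta_hyper`, HYPO when beta < `theta_hypo`,
#' INTERMEDIATE otherwise; both inequalities strict, so beta = 0.7 is
#' INTERMEDIATE. Vectorised; NA beta gives NA state.
#'
#' @param mean_beta Numeric vector of beta values in `[0, 1]`.
#' @param theta_hyper,theta_hypo State thresholds (defaults 0.7 / 0.3).
#' @return Character vector of "HYPER"/"HYPO"/"INTERMEDIATE".
#' @export
call_state <- function(mean_beta, theta_hyper = 0.7, theta_hypo = 0.3) {
  if (any(!is.na(mean_beta) & (mean_beta < 0 | mean_beta > 1))) {
    stop("beta values must lie in [0, 1]")
  }
  out <- rep(NA_character_, length(mean_beta))
  ok <- !is.na(mean_beta)
  out[ok] <- "INTERMEDIATE"
  out[ok & mean_beta > theta_hyper] <- "HYPER"
  out[ok & mean_beta < theta_hypo] <- "HYPO"
  out
}

#' Map (fibroblast, ESC, iPSC) state triples to aberration classes
#'
#' Total function over state triples: the four clear-state combinations
#' in which the iPSC state differs from the ESC state map to Classes
#' I-IV; every combination involving INTERMEDIATE (or NA), and every
#' combination where the iPSC matches the ESC state, is UNCLASSIFIED.
#' Vectorised over triples.
#'
#' @param fib,esc,ipsc Character vectors of state calls.
#' @return Character vector of "CLASS_I".."CLASS_IV"/"UNCLASSIFIED".
#' @export
classify_aberration <- function(fib, esc, ipsc) {
  n <- max(length(fib), length(esc), length(ipsc))
  fib <- rep_len(fib, n); esc <- rep_len(esc, n); ipsc <- rep_len(ipsc, n)
  out <- rep("UNCLASSIFIED", n)
  out[fib == "HYPO" & esc == "HYPO" & ipsc == "HYPER"] <- "CLASS_I"
  out[fib == "HYPO" & esc == "HYPER" & ipsc == "HYPO"] <- "CLASS_II"
  out[fib == "HYPER" & esc == "HYPO" & ipsc == "HYPER"] <- "CLASS_III"
  out[fib == "HYPER" & esc == "HYPER" & ipsc == "HYPO"] <- "CLASS_IV"
  out[is.na(fib) | is.na(esc) | is.na(ipsc)] <- "UNCLASSIFIED"
  out
}

## Classify a set of probes given the iPSC group(s) providing the iPSC
## mean; shared helper of the two public classification entry points.
classify_probes <- function(matrix, sheet, probe_ids, ipsc_groups, scope,
                            theta_hyper = 0.7, theta_hypo = 0.3) {
  fib_mean <- group_mean_beta(matrix, sheet, "FIB")[probe_ids]
  esc_mean <- group_mean_beta(matrix, sheet, "ESC")[probe_ids]
  ipsc_ids <- samples_in_group(sheet, ipsc_groups)
  ipsc_mean <- rowMeans(matrix[probe_ids, ipsc_ids, drop = FALSE],
                        na.rm = TRUE)
  fib_state <- call_state(fib_mean, theta_hyper, theta_hypo)
  esc_state <- call_state(esc_mean, theta_hyper, theta_hypo)
  ipsc_state <- call_state(ipsc_mean, theta_hyper, theta_hypo)
  data.frame(probe_id = probe_ids,
             fib_state = fib_state, esc_state = esc_state,
             ipsc_state = ipsc_state,
             class = classify_aberration(fib_state, esc_state, ipsc_state),
             scope = rep(scope, length(probe_ids)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify aberrations shared by both iPSC panels
#'
#' Takes the significant probes of a pooled-iPSC versus ESC differential
#' call and classifies each by the fibroblast mean, ESC mean and pooled
#' iPSC mean states.
#'
#' @param matrix Beta matrix.
#' @param sheet Sample sheet.
#' @param diff [call_differential()] result computed with
#'   `group_a = c("Y_IPSC", "T_IPSC")`, `group_b = "ESC"`.
#' @param theta_hyper,theta_hypo State thresholds.
#' @return data.frame of classified probes (`scope = "shared"`).
#' @export
shared_aberrations <- function(matrix, sheet, diff,
                               theta_hyper = 0.7, theta_hypo = 0.3) {
  sig <- diff$probe_id[diff$significant]
  if (length(sig) == 0) {
    return(classify_probes(matrix, sheet, character(0),
                           c("Y_IPSC", "T_IPSC"), "shared",
                           theta_hyper, theta_hypo))
  }
  classify_probes(matrix, sheet, sig, c("Y_IPSC", "T_IPSC"), "shared",
                  theta_hyper, theta_hypo)
}

#' Classify factor-specific aberrations (Y-iPSC vs T-iPSC)
#'
#' Each probe significant in the Y-versus-T differential call is
#' classified twice: once with the Y-iPSC group mean as the iPSC state
#' (`scope = "Y_specific"`) and once with the T-iPSC mean
#' (`scope = "T_specific"`), so each subtype's own aberration relative to
#' the fibroblast and ESC references is reported. A subtype whose state
#' matches the ESC state is UNCLASSIFIED for that scope (it is not
#' aberrant there).
#'
#' @param matrix Beta matrix.
#' @param sheet Sample sheet.
#' @param diff [call_differential()] result for Y_IPSC vs T_IPSC.
#' @param theta_hyper,theta_hypo State thresholds.
#' @return data.frame of classified probes, two rows per significant
#'   probe.
#' @export
factor_specific_aberrations <- function(matrix, sheet, diff,
                                        theta_hyper = 0.7,
                                        theta_hypo = 0.3) {
  sig <- diff$probe_id[diff$significant]
  y <- classify_probes(matrix, sheet, sig, "Y_IPSC", "Y_specific",
                       theta_hyper, theta_hypo)
  t <- classify_probes(matrix, sheet, sig, "T_IPSC", "T_specific",
                       theta_hyper, theta_hypo)
  rbind(y, t)
}

#' Class composition of a classified probe set
#'
#' Counts and fractions per named class, fractions taken over classified
#' (non-UNCLASSIFIED) probes so they sum to 1.
#'
#' @param probes data.frame with a `class` column.
#' @return data.frame with columns `class`, `count`, `fraction` (empty if
#'   no probe carries a named class).
#' @export
class_composition <- function(probes) {
  named <- probes$class[probes$class %in% ABERRATION_CLASSES]
  if (length(named) == 0) {
    return(data.frame(class = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  counts <- table(factor(named, levels = ABERRATION_CLASSES))
  data.frame(class = names(counts), count = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed/expected aberration-class ratios under a uniform-draw null
#'
#' Asks whether the composition of an observed aberrant set is skewed
#' across the four classes relative to chance. The eligible universe is
#' every probe whose fibroblast and ESC mean states are both clear (not
#' INTERMEDIATE). Under the null, sets of the observed size are drawn
#' uniformly without replacement from this universe and each drawn probe
#' is assigned the class implied by its (FIB, ESC) states with the
#' aberrant iPSC state taken as flipped relative to ESC — so (HYPO, HYPO)
#' yields Class I, (HYPO, HYPER) Class II, (HYPER, HYPO) Class III and
#' (HYPER, HYPER) Class IV. The ratio is observed count over mean null
#' count; the empirical p is the two-sided plus-one permutation
#' probability, never zero.
#'
#' @param probes Classified probe set (only named-class rows are used).
#' @param matrix Beta matrix (defines the universe).
#' @param sheet Sample sheet.
#' @param n_draws Number of null draws (default 10000).
#' @param seed Integer RNG seed.
#' @param theta_hyper,theta_hypo State thresholds.
#' @return data.frame with columns `class`, `observed`, `expected`,
#'   `ratio`, `p_value`.
#' @export
observed_expected_class_ratio <- function(probes, matrix, sheet,
                                          n_draws = 10000, seed = 1,
                                          theta_hyper = 0.7,
                                          theta_hypo = 0.3) {
  fib_state <- call_state(group_mean_beta(matrix, sheet, "FIB"),
                          theta_hyper, theta_hypo)
  esc_state <- call_state(group_mean_beta(matrix, sheet, "ESC"),
                          theta_hyper, theta_hypo)
  eligible <- !is.na(fib_state) & !is.na(esc_state) &
    fib_state != "INTERMEDIATE" & esc_state != "INTERMEDIATE"
  ## class implied by (FIB, ESC) when the iPSC state flips vs ESC
  implied <- classify_aberration(fib_state[eligible], esc_state[eligible],
                                 flip_state(esc_state[eligible]))
  observed <- probes[probes$class %in% ABERRATION_CLASSES, , drop = FALSE]
  k <- nrow(observed)
  if (k == 0) stop("no named-class probes in the observed set")
  if (k > length(implied)) stop("observed set larger than eligible universe")
  obs_counts <- table(factor(observed$class, levels = ABERRATION_CLASSES))

  cls_idx <- as.integer(factor(implied, levels = ABERRATION_CLASSES))
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      tabulate(cls_idx[sample.int(length(cls_idx), k)], nbins = 4)
    }, integer(4))
  })  # 4 x n_draws
  expected <- rowMeans(null_counts)
  p <- vapply(1:4, function(c) {
    o <- as.integer(obs_counts[c])
    p_hi <- (sum(null_counts[c, ] >= o) + 1) / (n_draws + 1)
    p_lo <- (sum(null_counts[c, ] <= o) + 1) / (n_draws + 1)
    min(1, 2 * min(p_hi, p_lo))
  }, numeric(1))
  data.frame(class = ABERRATION_CLASSES,
             observed = as.integer(obs_counts),
             expected = expected,
             ratio = ifelse(expected > 0,
                            as.integer(obs_counts) / expected, NA_real_),
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}
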