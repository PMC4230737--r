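## Synthetic beta-value data with planted aberration ground truth.
##
## The simulator emulates the study design the pipeline targets: one
## parental fibroblast batch (profiled as technical replicates), a panel
## of reference ESC lines, and two iPSC panels made with different
## reprogramming-factor cocktails. Each probe carries a latent methylation
## state per group (HYPER/HYPO); per-sample beta values are drawn from a
## beta distribution around the state mean.

## Aberration classes as (FIB, ESC, aberrant-iPSC) state triples.
CLASS_STATE_TABLE <- list(
  CLASS_I   = c(FIB = "HYPO",  ESC = "HYPO",  IPSC = "HYPER"), # de novo methylation
  CLASS_II  = c(FIB = "HYPO",  ESC = "HYPER", IPSC = "HYPO"),  # failed methylation
  CLASS_III = c(FIB = "HYPER", ESC = "HYPO",  IPSC = "HYPER"), # failed demethylation
  CLASS_IV  = c(FIB = "HYPER", ESC = "HYPER", IPSC = "HYPO")   # de novo demethylation
)

## Ground-truth labels: no aberration, aberration shared by both iPSC
## panels, or specific to the Y or T panel.
TRUTH_LABELS <- c("NULL",
                  paste0("SHARED_", c("I", "II", "III", "IV")),
                  paste0("Y_", c("I", "II", "III", "IV")),
                  paste0("T_", c("I", "II", "III", "IV")))

## Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default planted class fractions
#'
#' The defaults emulate the aberration landscape the pipeline is designed
#' to detect: shared aberrations total 1.2% of probes split roughly
#' 62/32/3/3 across Classes II/III/I/IV; factor-specific aberrations total
#' ~0.9%, with the Y panel biased to failed demethylation (Class III) and
#' the T panel to failed methylation (Class II); everything else is NULL,
#' keeping the overall iPSC divergence from the ESC reference below 2% of
#' probes while the parental fibroblasts differ at ~17%.
#'
#' @return Named numeric vector over [TRUTH_LABELS], summing to 1.
#' @export
default_class_fractions <- function() {
  fr <- c("NULL" = 0,
          SHARED_I = 0.0004, SHARED_II = 0.0074, SHARED_III = 0.0038,
          SHARED_IV = 0.0004,
          Y_I = 0.0004, Y_II = 0.0008, Y_III = 0.0030, Y_IV = 0.0004,
          T_I = 0.0004, T_II = 0.0030, T_III = 0.0008, T_IV = 0.0004)
  fr[["NULL"]] <- 1 - sum(fr)
  fr[TRUTH_LABELS]
}

#' Simulation configuration
#'
#' @param n_probes Number of probes to simulate.
#' @param group_sizes Named vector of biological group sizes; defaults to
#'   the study design (1 fibroblast pool, 5 ESC lines, 9 Y-iPSC and
#'   6 T-iPSC clones).
#' @param fib_replicates Technical replicates profiled for each fibroblast
#'   pool, so rank tests against the single parental batch are defined.
#' @param class_fractions Named fractions over [TRUTH_LABELS] summing to 1.
#' @param noise_concentration Beta-distribution concentration kappa of
#'   per-sample noise around the state mean (sd ~ 0.036 at mean 0.15 for
#'   kappa = 100).
#' @param state_means Named vector `c(HYPER=, HYPO=)`; HYPER must exceed
#'   0.7 and HYPO fall below 0.3 so planted states are recoverable at the
#'   state-calling thresholds.
#' @param null_discordance Probability that a NULL probe's fibroblast
#'   state differs from its ESC state (tissue-specific methylation; the
#'   default 0.17 makes ~17% of probes differ between fibroblasts and
#'   pluripotent cells).
#' @param esc_hyper_prob Probability a NULL probe is hypermethylated in
#'   ESCs (pluripotent genomes are predominantly methylated).
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 2000,
                              group_sizes = c(FIB = 1, ESC = 5,
                                              Y_IPSC = 9, T_IPSC = 6),
                              fib_replicates = 3,
                              class_fractions = default_class_fractions(),
                              noise_concentration = 100,
                              state_means = c(HYPER = 0.85, HYPO = 0.15),
                              null_discordance = 0.17,
                              esc_hyper_prob = 0.55,
                              seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  miss <- setdiff(names(class_fractions), TRUTH_LABELS)
  if (length(miss)) stop("unknown class fraction label(s): ",
                         paste(miss, collapse = ", "))
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (state_means[["HYPER"]] <= 0.7 || state_means[["HYPO"]] >= 0.3) {
    stop("state_means must satisfy HYPER > 0.7 and HYPO < 0.3")
  }
  if (noise_concentration <= 0) stop("noise_concentration must be positive")
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  structure(list(n_probes = as.integer(n_probes),
                 group_sizes = group_sizes,
                 fib_replicates = as.integer(fib_replicates),
                 class_fractions = class_fractions,
                 noise_concentration = noise_concentration,
                 state_means = state_means,
                 null_discordance = null_discordance,
                 esc_hyper_prob = esc_hyper_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Flip a state relative to a reference state.
flip_state <- function(state) ifelse(state == "HYPER", "HYPO", "HYPER")

## Latent per-group states for every probe given its truth label.
## Returns a matrix probes x c(FIB, ESC, Y_IPSC, T_IPSC) of "HYPER"/"HYPO".
truth_states <- function(labels, esc_hyper_prob, null_discordance) {
  n <- length(labels)
  st <- matrix(NA_character_, n, 4,
               dimnames = list(NULL, c("FIB", "ESC", "Y_IPSC", "T_IPSC")))
  is_null <- labels == "NULL"
  if (any(is_null)) {
    esc <- ifelse(stats::runif(sum(is_null)) < esc_hyper_prob,
                  "HYPER", "HYPO")
    discord <- stats::runif(sum(is_null)) < null_discordance
    st[is_null, "ESC"] <- esc
    st[is_null, "FIB"] <- ifelse(discord, flip_state(esc), esc)
    st[is_null, "Y_IPSC"] <- esc   # faithfully reprogrammed
    st[is_null, "T_IPSC"] <- esc
  }
  for (cls in names(CLASS_STATE_TABLE)) {
    tab <- CLASS_STATE_TABLE[[cls]]
    roman <- sub("CLASS_", "", cls)
    for (scope in c("SHARED", "Y", "T")) {
      lab <- paste0(scope, "_", roman)
      idx <- labels == lab
      if (!any(idx)) next
      st[idx, "FIB"] <- tab[["FIB"]]
      st[idx, "ESC"] <- tab[["ESC"]]
      st[idx, "Y_IPSC"] <- if (scope %in% c("SHARED", "Y"))
        tab[["IPSC"]] else tab[["ESC"]]
      st[idx, "T_IPSC"] <- if (scope %in% c("SHARED", "T"))
        tab[["IPSC"]] else tab[["ESC"]]
    }
  }
  st
}

## Draw beta values around state means: beta(mu*kappa, (1-mu)*kappa).
rbeta_mean <- function(n, mu, kappa) {
  stats::rbeta(n, shape1 = mu * kappa, shape2 = (1 - mu) * kappa)
}

#' Generate a synthetic methylation dataset with planted ground truth
#'
#' Produces a beta matrix, sample sheet, probe annotation and per-probe
#' truth labels. Each probe receives a latent HYPER/HYPO state per group
#' consistent with its label (e.g. a `Y_III` probe is HYPER in FIB, HYPO
#' in ESC, HYPER in Y-iPSC and HYPO in T-iPSC); per-sample betas are drawn
#' from a beta distribution with the state mean and the configured
#' concentration. Identical config and seed give identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `beta` (matrix), `sheet`, `annotation`,
#'   `truth` (data.frame probe_id, label).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_probes
    probe_ids <- sprintf("cg%07d", seq_len(n))

    labels <- sample(TRUTH_LABELS, n, replace = TRUE,
                     prob = config$class_fractions[TRUTH_LABELS])
    states <- truth_states(labels, config$esc_hyper_prob,
                           config$null_discordance)

    ## sample layout
    gs <- config$group_sizes
    n_fib_cols <- gs[["FIB"]] * config$fib_replicates
    sample_id <- c(sprintf("FIB_%d", seq_len(n_fib_cols)),
                   sprintf("ESC_%d", seq_len(gs[["ESC"]])),
                   sprintf("YIPSC_%d", seq_len(gs[["Y_IPSC"]])),
                   sprintf("TIPSC_%d", seq_len(gs[["T_IPSC"]])))
    group <- rep(c("FIB", "ESC", "Y_IPSC", "T_IPSC"),
                 times = c(n_fib_cols, gs[["ESC"]],
                           gs[["Y_IPSC"]], gs[["T_IPSC"]]))
    sheet <- sample_sheet(sample_id, group)

    mu <- config$state_means
    mean_mat <- matrix(0, n, length(sample_id),
                       dimnames = list(probe_ids, sample_id))
    for (j in seq_along(sample_id)) {
      mean_mat[, j] <- ifelse(states[, group[j]] == "HYPER",
                              mu[["HYPER"]], mu[["HYPO"]])
    }
    values <- matrix(rbeta_mean(length(mean_mat), as.vector(mean_mat),
                                config$noise_concentration),
                     n, length(sample_id),
                     dimnames = dimnames(mean_mat))

    ## annotation: positions over 22 autosomes, context frequencies
    ## loosely resembling the 450K platform, genes for 96% of probes
    chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
    pos <- sample.int(2e8, n, replace = TRUE)
    dup <- duplicated(paste(chrom, pos))
    while (any(dup)) {
      pos[dup] <- sample.int(2e8, sum(dup), replace = TRUE)
      dup <- duplicated(paste(chrom, pos))
    }
    ctx <- sample(ISLAND_CONTEXTS, n, replace = TRUE,
                  prob = c(0.31, 0.23, 0.10, 0.36))
    gene_pool <- sprintf("GENE%05d", seq_len(max(1L, n %/% 4L)))
    gene <- sample(gene_pool, n, replace = TRUE)
    tssd <- round(stats::rnorm(n, 0, 8000))
    no_gene <- stats::runif(n) < 0.04
    gene[no_gene] <- NA
    tssd[no_gene] <- NA
    ann <- probe_annotation(probe_ids, chrom, pos, ctx, gene, tssd)

    list(beta = beta_matrix(values),
         sheet = sheet,
         annotation = ann,
         truth = data.frame(probe_id = probe_ids, label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Generate binding peaks with controllable enrichment over aberrant probes
#'
#' Each probe's position is covered by a fixed-width peak with baseline
#' probability `baseline_prob`; for probes whose truth label is in
#' `aberrant_labels` the odds of coverage are multiplied by
#' `enrichment_odds`. `enrichment_odds = 1` gives a null peak set.
#'
#' @param truth Ground-truth data.frame from [generate_dataset()].
#' @param annotation Matching probe annotation.
#' @param factor_name Transcription-factor name for the peak set.
#' @param enrichment_odds Positive odds ratio of peak coverage,
#'   aberrant vs NULL probes.
#' @param baseline_prob Coverage probability for non-aberrant probes.
#' @param peak_width Peak width in bp (peaks are centred on probe
#'   positions).
#' @param aberrant_labels Truth labels counted as aberrant; defaults to
#'   all non-NULL labels.
#' @param seed Integer RNG seed.
#' @return A `peak_set`.
#' @export
generate_peaks <- function(truth, annotation, factor_name,
                           enrichment_odds = 1, baseline_prob = 0.1,
                           peak_width = 400,
                           aberrant_labels = setdiff(TRUTH_LABELS, "NULL"),
                           seed = 1) {
  if (!is.character(factor_name) || !nzchar(factor_name)) {
    stop("factor_name must be a non-empty string")
  }
  if (enrichment_odds <= 0) stop("enrichment_odds must be positive")
  with_seed(seed, {
    ann <- annotation[match(truth$probe_id, annotation$probe_id), ]
    odds0 <- baseline_prob / (1 - baseline_prob)
    odds1 <- odds0 * enrichment_odds
    p1 <- odds1 / (1 + odds1)
    p <- ifelse(truth$label %in% aberrant_labels, p1, baseline_prob)
    covered <- stats::runif(nrow(ann)) < p
    if (!any(covered)) {
      return(peak_set(character(0), integer(0), integer(0), factor_name))
    }
    half <- peak_width %/% 2
    start0 <- pmax(0L, ann$pos[covered] - 1L - half)
    end0 <- start0 + as.integer(peak_width)
    peak_set(ann$chrom[covered], start0, end0, factor_name)
  })
}

#' Simulate an RRBS profile from array beta values
#'
#' Draws binomial methylated-read counts at probe coordinates, the
#' generative model under which array and sequencing estimates measure
#' the same absolute methylation level.
#'
#' @param beta Named numeric vector of beta values (names = probe ids).
#' @param annotation Probe annotation supplying coordinates.
#' @param depth Sequencing depth per CpG (constant).
#' @param seed Integer RNG seed.
#' @return RRBS profile data.frame (see [rrbs_profile()]).
#' @export
simulate_rrbs <- function(beta, annotation, depth = 30, seed = 1) {
  keep <- !is.na(beta)
  beta <- beta[keep]
  ann <- annotation[match(names(beta), annotation$probe_id), ]
  with_seed(seed, {
    meth <- stats::rbinom(length(beta), size = depth, prob = beta)
    rrbs_profile(ann$chrom, ann$pos, meth, rep(depth, length(beta)))
  })
}

#' Simulate a beta matrix around given per-probe/per-sample means
#'
#' Low-level sampler shared by the tumour/normal comparison drivers:
#' betas are drawn from a beta distribution with the supplied means and
#' concentration, probe and sample names taken from `mean_matrix`.
#'
#' @param mean_matrix Numeric matrix of means in (0, 1) with dimnames.
#' @param concentration Beta-distribution concentration kappa.
#' @param seed Integer RNG seed.
#' @return A validated beta matrix.
#' @export
simulate_beta_matrix <- function(mean_matrix, concentration = 100,
                                 seed = 1) {
  with_seed(seed, {
    values <- matrix(rbeta_mean(length(mean_matrix),
                                as.vector(mean_matrix), concentration),
                     nrow(mean_matrix), ncol(mean_matrix),
                     dimnames = dimnames(mean_matrix))
    beta_matrix(values)
  })
}
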