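# Small in-code fixtures shared across test files.

# A compact simulation config for fast tests.
small_config <- function(seed = 1, n_probes = 600, ...) {
  simulation_config(n_probes = n_probes, seed = seed, ...)
}

# Class fractions planting only the given labels at the given fractions,
# remainder NULL.
plant_fractions <- function(...) {
  fr <- c(...)
  base <- setNames(rep(0, length(methaberr:::TRUTH_LABELS)),
                   methaberr:::TRUTH_LABELS)
  base[names(fr)] <- fr
  base[["NULL"]] <- 1 - sum(fr)
  base
}

# Hand-built beta matrix with constant group plateaus: one column block
# per group, every probe at the state mean given in `group_means`
# (probes x groups matrix).
plateau_matrix <- function(group_means, group_sizes) {
  stopifnot(ncol(group_means) == length(group_sizes))
  cols <- list()
  ids <- character(0)
  for (g in seq_along(group_sizes)) {
    for (s in seq_len(group_sizes[g])) {
      cols[[length(cols) + 1]] <- group_means[, g]
      ids <- c(ids, sprintf("%s_%d", names(group_sizes)[g], s))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  rownames(m) <- rownames(group_means)
  m
}

# Minimal annotation for a vector of probe ids placed every 1000 bp on
# one chromosome.
simple_annotation <- function(probe_ids, chrom = "chr1",
                              start_pos = 10000, spacing = 1000,
                              context = "open_sea", gene = NA,
                              tss = NA) {
  probe_annotation(probe_ids, chrom,
                   start_pos + spacing * (seq_along(probe_ids) - 1),
                   rep(context, length.out = length(probe_ids)),
                   rep(gene, length.out = length(probe_ids)),
                   rep(tss, length.out = length(probe_ids)))
}
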