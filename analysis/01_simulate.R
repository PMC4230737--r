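#!/usr/bin/env Rscript
# Simulate the study design: one fibroblast batch (3 technical
# replicates), 5 reference ESC lines, 9 Y-iPSC and 6 T-iPSC clones over
# 20,000 probes, with aberrations planted at the default class fractions,
# plus one binding-peak set per reprogramming factor. NANOG peaks are
# planted with strong targeting of aberrant CpGs, OCT4 with moderate,
# the rest are null. Writes all pipeline inputs under results/data/.

library(methaberr)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_probes = 20000, seed = 1)
sim <- generate_dataset(cfg)

write_beta_matrix(sim$beta, file.path(out, "beta.tsv"))
write_results_table(sim$sheet, file.path(out, "samples.tsv"))
write_results_table(sim$annotation, file.path(out, "annotation.tsv"))
write_results_table(sim$truth, file.path(out, "ground_truth.tsv"))

odds <- c(OCT4 = 4, SOX2 = 1, NANOG = 12, KLF4 = 1, cMYC = 1)
for (i in seq_along(odds)) {
  fac <- names(odds)[i]
  pk <- generate_peaks(sim$truth, sim$annotation, fac,
                       enrichment_odds = odds[[i]], seed = 1 + i)
  write_bed_peaks(pk, file.path(out, paste0("peaks_", fac, ".bed")))
  cat(sprintf("%-6s %6d peaks (planted odds %g)\n", fac, nrow(pk),
              odds[[i]]))
}

cat(sprintf("beta matrix: %d probes x %d samples\n",
            nrow(sim$beta), ncol(sim$beta)))
print(table(sim$truth$label))
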