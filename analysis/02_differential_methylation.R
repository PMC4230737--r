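#!/usr/bin/env Rscript
# Differential methylation analysis: how far does each cell type sit
# from the ESC reference, and which CpGs separate the two iPSC panels?
# Fibroblasts should diverge from ESCs at a large fraction of CpGs
# (tissue-specific methylation) while reprogrammed cells should differ
# at only a small fraction, with an asymmetric Y-vs-T signature.

library(methaberr)

dat <- "results/data"
out <- "results"
mat <- read_beta_matrix(file.path(dat, "beta.tsv"))
sheet <- read_sample_sheet(file.path(dat, "samples.tsv"))

## global methylation landscape (bimodal betas)
ss <- methylation_state_summary(mat)
write_results_table(ss, file.path(out, "state_summary.tsv"))

## per-sample divergence from the ESC mean (delta >= 0.2)
div <- rbind(
  data.frame(group = "FIB",
             fraction = fraction_divergent(mat, sheet, "FIB")),
  data.frame(group = "Y_IPSC",
             fraction = fraction_divergent(mat, sheet, "Y_IPSC")),
  data.frame(group = "T_IPSC",
             fraction = fraction_divergent(mat, sheet, "T_IPSC")))
div$sample_id <- rownames(div)
write_results_table(div, file.path(out, "divergence_from_esc.tsv"))
cat(sprintf("divergence from ESC: FIB %.1f%%, iPSC %.2f%%\n",
            100 * mean(div$fraction[div$group == "FIB"]),
            100 * mean(div$fraction[div$group != "FIB"])))

## pooled iPSC vs ESC (shared aberrations)
diff_shared <- call_differential(mat, sheet, c("Y_IPSC", "T_IPSC"), "ESC")
write_results_table(diff_shared, file.path(out, "diffmeth_ipsc_vs_esc.tsv"))
cat(sprintf("iPSC vs ESC: %d significant CpGs of %d tested\n",
            sum(diff_shared$significant), nrow(diff_shared)))

## Y-iPSC vs T-iPSC (factor-specific aberrations)
diff_yt <- call_differential(mat, sheet, "Y_IPSC", "T_IPSC")
write_results_table(diff_yt, file.path(out, "diffmeth_y_vs_t.tsv"))
n_up_y <- sum(diff_yt$significant & diff_yt$delta_beta > 0)
n_up_t <- sum(diff_yt$significant & diff_yt$delta_beta < 0)
cat(sprintf(
  "Y vs T: %d significant CpGs (%d hypermethylated in Y, %d in T)\n",
  sum(diff_yt$significant), n_up_y, n_up_t))
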