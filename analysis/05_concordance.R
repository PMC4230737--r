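#!/usr/bin/env Rscript
# Sample-level structure and cross-platform concordance: correlation
# clustering should isolate the fibroblasts and separate ESCs from
# iPSCs; PCA should split Y- from T-iPSCs; RRBS counts resampled from
# one iPSC methylome should agree with the array betas at r > 0.95.

library(methaberr)

dat <- "results/data"
out <- "results"
mat <- read_beta_matrix(file.path(dat, "beta.tsv"))
sheet <- read_sample_sheet(file.path(dat, "samples.tsv"))
ann <- read_probe_annotation(file.path(dat, "annotation.tsv"))

cm <- pairwise_correlation_matrix(mat)
write_results_table(data.frame(sample_id = rownames(cm), cm,
                               check.names = FALSE),
                    file.path(out, "sample_correlation.tsv"))
cl <- cluster_samples(cm, k = 3)
write_results_table(data.frame(sample_id = names(cl), cluster = cl,
                               group = sheet$group[match(names(cl),
                                                         sheet$sample_id)]),
                    file.path(out, "sample_clusters.tsv"))
cat("cluster composition (k = 3):\n")
print(table(sheet$group[match(names(cl), sheet$sample_id)], cl))

pc <- pca_scores(mat[, samples_in_group(sheet,
                                        c("ESC", "Y_IPSC", "T_IPSC"))], 2)
write_results_table(data.frame(sample_id = rownames(pc), pc,
                               check.names = FALSE),
                    file.path(out, "pca_scores.tsv"))

## RRBS concordance for one Y-iPSC and one T-iPSC sample
for (s in c("YIPSC_1", "TIPSC_1")) {
  rr <- simulate_rrbs(mat[, s], ann, depth = 30,
                      seed = if (s == "YIPSC_1") 11 else 12)
  res <- rrbs_array_concordance(rr, mat[, s], ann, min_coverage = 5)
  cat(sprintf("%s: %d shared CpGs, Pearson r = %.3f\n",
              s, res$n_shared_cpgs, res$pearson_r))
}
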