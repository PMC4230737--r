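#!/usr/bin/env Rscript
# Classify significant CpGs into the four aberration classes, for
# aberrations shared by both iPSC panels and for each panel separately,
# then ask whether the class composition differs from chance: failure
# aberrations (Classes II/III) should be over-represented and de novo
# aberrations (Classes I/IV) depleted.

library(methaberr)

dat <- "results/data"
out <- "results"
mat <- read_beta_matrix(file.path(dat, "beta.tsv"))
sheet <- read_sample_sheet(file.path(dat, "samples.tsv"))
diff_shared <- utils::read.delim(file.path(out, "diffmeth_ipsc_vs_esc.tsv"))
diff_yt <- utils::read.delim(file.path(out, "diffmeth_y_vs_t.tsv"))

cls_shared <- shared_aberrations(mat, sheet, diff_shared)
write_results_table(cls_shared, file.path(out, "classified_shared.tsv"))
comp <- class_composition(cls_shared)
write_results_table(comp, file.path(out, "composition_shared.tsv"))
cat("shared aberration composition:\n")
print(transform(comp, pct = round(100 * fraction, 1)))

cls_factor <- factor_specific_aberrations(mat, sheet, diff_yt)
write_results_table(cls_factor,
                    file.path(out, "classified_factor_specific.tsv"))
for (sc in c("Y_specific", "T_specific")) {
  cc <- class_composition(cls_factor[cls_factor$scope == sc, ])
  write_results_table(cc, file.path(out, paste0("composition_",
                                                tolower(sc), ".tsv")))
  cat(sc, "composition:\n")
  print(transform(cc, pct = round(100 * fraction, 1)))
}

## observed vs expected class ratios under the uniform-draw null
oe <- observed_expected_class_ratio(cls_shared, mat, sheet,
                                    n_draws = 10000, seed = 1)
write_results_table(oe, file.path(out, "obs_exp_ratio_shared.tsv"))
cat("observed/expected class ratios (shared aberrations):\n")
print(oe)
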