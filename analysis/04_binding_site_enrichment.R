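#!/usr/bin/env Rscript
# Are aberrantly methylated CpGs concentrated at genes bound by the
# reprogramming factors? Gene-level permutation enrichment (10,000 draws
# without replacement from all probes, exact plus-one p-values) for each
# factor's peak set against each aberrant scope, plus the promoter-hit
# table, island-context enrichment, and the TSS-distance profile.

library(methaberr)

dat <- "results/data"
out <- "results"
ann <- read_probe_annotation(file.path(dat, "annotation.tsv"))
cls_shared <- utils::read.delim(file.path(out, "classified_shared.tsv"))
cls_factor <- utils::read.delim(file.path(out,
                                          "classified_factor_specific.tsv"))
all_cls <- rbind(cls_shared, cls_factor)

factors <- c("OCT4", "SOX2", "NANOG", "KLF4", "cMYC")
rows <- list()
hits <- list()
for (fac in factors) {
  pk <- read_bed_peaks(file.path(dat, paste0("peaks_", fac, ".bed")), fac)
  for (sc in unique(all_cls$scope)) {
    cp <- all_cls[all_cls$scope == sc, ]
    if (!any(cp$class %in% c("CLASS_I", "CLASS_II", "CLASS_III",
                             "CLASS_IV"))) next
    gl <- gene_level_enrichment(cp, ann, pk, w = 5000, B = 10000,
                                seed = 1)
    r <- gl$result
    rows[[paste(fac, sc)]] <- data.frame(
      factor = fac, scope = sc, observed_genes = r$observed_overlap,
      null_mean = r$null_mean, null_sd = r$null_sd,
      outside_null = r$outside_null, p_enrichment = r$p_enrichment,
      p_depletion = r$p_depletion)
    if (nrow(gl$hits)) {
      hits[[paste(fac, sc)]] <- data.frame(scope = sc, gl$hits)
    }
    cat(sprintf(
      "%-6s %-11s observed %3d genes (null %6.1f +/- %4.1f)  p_enr=%.2g%s\n",
      fac, sc, r$observed_overlap, r$null_mean, r$null_sd,
      r$p_enrichment, if (r$outside_null) "  [outside null]" else ""))
  }
}
write_results_table(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                    file.path(out, "enrichment_binding_sites.tsv"))
write_results_table(do.call(rbind, c(hits, list(make.row.names = FALSE))),
                    file.path(out, "gene_promoter_hits.tsv"))

ic <- island_context_enrichment(all_cls, ann, B = 2000, seed = 2)
write_results_table(ic, file.path(out, "island_context_enrichment.tsv"))

prof <- tss_distance_profile(all_cls, ann)
write_results_table(prof, file.path(out, "tss_distance_profile.tsv"))
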