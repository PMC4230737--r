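# methaberr

Detection, classification and interpretation of DNA methylation
aberrations in reprogrammed cells, from beta-value methylation-array
data.

When somatic cells are reprogrammed to induced pluripotent stem cells
(iPSCs), the DNA methylation landscape must be rewritten to match that
of embryonic stem cells (ESCs). The rewrite is imperfect, and the *type*
of error is informative: a CpG can retain parental methylation that
should have been erased (failed demethylation — epigenetic memory), miss
methylation it should have gained (failed methylation), or change de
novo in a way neither the parental cells nor ESCs show. `methaberr` is
for stem-cell and epigenomics researchers who want to quantify these
aberrations, compare them between reprogramming-factor cocktails
(Yamanaka "Y" vs Thomson "T"), and ask where in the genome they land.

## What it computes

For a beta matrix β (probes × samples, β = M/(M+U) ∈ [0,1]) with groups
FIB (parental fibroblasts), ESC, Y_IPSC, T_IPSC:

* **Differential methylation** — per probe, Δβ = mean(A) − mean(B),
  two-sided Wilcoxon rank-sum p, Benjamini–Hochberg FDR array-wide;
  significant iff |Δβ| > 0.2 and q < 0.05 (strict).
* **Aberration classes** — group states from mean beta (hyper > 0.7,
  hypo < 0.3, strict); each significant CpG is classified from the
  (FIB, ESC, iPSC) state triple: Class I de novo methylation
  (hypo, hypo, hyper), Class II failed methylation (hypo, hyper, hypo),
  Class III failed demethylation (hyper, hypo, hyper), Class IV de novo
  demethylation (hyper, hyper, hypo); everything else UNCLASSIFIED.
  Shared (pooled iPSC vs ESC) and factor-specific (Y vs T, classified
  per subtype) scopes.
* **Permutation enrichment** — overlap of aberrant CpGs/genes with
  transcription-factor binding peaks against 10,000 uniform
  without-replacement redraws from all array probes; exact plus-one
  p-values (never zero); gene-level counting within a ±5 kb TSS window;
  island-context and TSS-distance profiles; observed/expected class
  ratios under a uniform-draw null.
* **Concordance & cancer** — correlation clustering and PCA of sample
  methylomes; RRBS-vs-array Pearson r at CpGs with ≥ 5× coverage;
  tumour-minus-normal Δβ profiling at aberrant CpGs with a permutation
  test of Class I overlap with cancer-hypermethylated CpGs.
* **Synthetic data** — `generate_dataset()` plants ground-truth
  aberrations under the study design (1 fibroblast batch × 3 technical
  replicates, 5 ESC, 9 Y-iPSC, 6 T-iPSC) with beta-distributed noise;
  `generate_peaks()` plants peak sets with a controllable enrichment
  odds ratio, so every stage is testable without downloads.

## Worked example

```r
library(methaberr)

sim <- generate_dataset(simulation_config(n_probes = 20000, seed = 1))
diff <- call_differential(sim$beta, sim$sheet,
                          c("Y_IPSC", "T_IPSC"), "ESC")
sum(diff$significant)
#> [1] 248

cls <- shared_aberrations(sim$beta, sim$sheet, diff)
class_composition(cls)
#>       class count   fraction
#> 1   CLASS_I     6 0.02419355
#> 2  CLASS_II   146 0.58870968
#> 3 CLASS_III    90 0.36290323
#> 4  CLASS_IV     6 0.02419355

observed_expected_class_ratio(cls, sim$beta, sim$sheet,
                              n_draws = 10000, seed = 1)
#>       class observed expected      ratio    p_value
#> 1   CLASS_I        6  89.8440 0.06678242 0.00019998
#> 2  CLASS_II      146  25.6377 5.69473861 0.00019998
#> 3 CLASS_III       90  21.2031 4.24466234 0.00019998
#> 4  CLASS_IV        6 111.3152 0.05390099 0.00019998
```

Of 20,000 simulated CpGs, 248 are significantly different between
pooled iPSCs and ESCs; ~59% are Class II and ~36% Class III, and the
ratio table shows failure aberrations (II/III) at 4–6× their chance
expectation while de novo aberrations (I/IV) are strongly depleted —
the permutation floor p of 2/10001 on all four. Peak enrichment on the
same dataset (planted NANOG targeting, odds 12):

```r
pk <- generate_peaks(sim$truth, sim$annotation, "NANOG",
                     enrichment_odds = 12, seed = 4)
gene_level_enrichment(cls, sim$annotation, pk, B = 10000, seed = 1)$result
#> Permutation enrichment [NANOG]: observed 54 of 248 (null 12.47 +/- 3.43)
#>   p_enrichment = 9.999e-05, p_depletion = 1 (B = 10000) [outside null range]
```

The observed 54 target genes fall entirely outside the 10,000-draw null
— the strongest call the permutation design supports.

The numbered scripts under `analysis/` run the full narrative (simulate
→ differential → classify → enrichment → concordance → cancer
comparison), printing these summaries and writing every table under
`results/`. `run_demo(out_dir, seed)` does the same end-to-end in one
call with a checksum manifest and provenance log.

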