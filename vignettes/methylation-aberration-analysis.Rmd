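---
title: "Detecting and classifying DNA methylation aberrations in reprogrammed cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying DNA methylation aberrations in reprogrammed cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Reprogramming somatic cells into induced pluripotent stem cells (iPSCs)
requires erasing tissue-specific DNA methylation and re-establishing the
methylation landscape of pluripotent cells. This process is imperfect:
iPSC methylomes carry recurrent aberrations relative to embryonic stem
cells (ESCs), and the type of aberration carries mechanistic meaning —
a CpG can fail to be demethylated (retaining parental methylation, the
signature of epigenetic memory), fail to be methylated, or acquire a
methylation change de novo that neither the parental cells nor ESCs
show. Whether the choice of reprogramming-factor cocktail (Yamanaka:
OCT4/SOX2/KLF4/cMYC, "Y"; Thomson: OCT4/SOX2/NANOG/LIN28, "T") shifts
the balance between these aberration types is the question this package
operationalises.

`methaberr` implements the complete analysis as reusable, tested
functions over beta-value methylation-array data: per-probe differential
methylation, a four-class aberration taxonomy, permutation-based
enrichment of aberrations at transcription-factor binding regions,
genomic-context profiling, sequencing–array concordance, and
tumour-versus-normal delta-beta comparison — all validated end-to-end on
synthetic data with planted ground truth.

## The model

The substrate is a beta value per CpG and sample, the methylated signal
fraction $\beta = M/(M+U) \in [0,1]$. All inference operates on betas;
intensity-level preprocessing is out of scope (`compute_beta()` is kept
as a utility).

**Differential methylation.** For two groups $A$, $B$ the effect size is
$\Delta\beta = \bar\beta_A - \bar\beta_B$ of group means. Evidence is a
two-sided Wilcoxon rank-sum (Mann–Whitney) p-value per probe, followed
by Benjamini–Hochberg FDR across all tested probes (array-wide). A probe
is differentially methylated when

$$|\Delta\beta| > 0.2 \quad\text{and}\quad q < 0.05,$$

both inequalities strict, so a difference of exactly 0.2 is not called.
The rank-sum test (rather than a signed-rank test) is the right choice
here because the groups are independent samples, not paired
measurements; this is stated prominently because the two names are
easily conflated in methylation work.

**State calling.** A group is hypermethylated at a CpG when its mean
beta exceeds 0.7, hypomethylated below 0.3, and intermediate otherwise
(strict inequalities). The group state is the state of the group mean,
not a per-sample majority vote: group means are what the downstream
class definitions describe, and the mean is monotone in the underlying
signal.

**Aberration classes.** Each differential CpG is classified from the
(fibroblast, ESC, iPSC) state triple:

| Class | FIB | ESC | iPSC | interpretation |
|-------|-----|-----|------|----------------|
| I   | hypo  | hypo  | hyper | de novo methylation |
| II  | hypo  | hyper | hypo  | failed methylation |
| III | hyper | hypo  | hyper | failed demethylation |
| IV  | hyper | hyper | hypo  | de novo demethylation |

Any triple containing an intermediate state, and any triple in which the
iPSC matches the ESC state, is UNCLASSIFIED: the taxonomy only speaks
about clear states, and forcing ambiguous probes into a class would
contaminate the composition estimates. Classes II and III are *failure*
aberrations (inadequate change of the parental state — epigenetic
memory); Classes I and IV are *de novo* aberrations.

Shared aberrations classify the significant probes of pooled-iPSC vs
ESC using the pooled iPSC mean. Factor-specific aberrations classify
each significant Y-vs-T probe twice — once with the Y mean and once with
the T mean as the iPSC state — so each panel's own aberration relative
to FIB and ESC is reported; a panel whose state matches ESC is not
aberrant there and is UNCLASSIFIED for that scope. Per-subtype means
(rather than the pooled mean) are used because the question is precisely
which subtype deviates.

**Permutation enrichment.** Whether aberrant CpGs concentrate at regions
bound by reprogramming factors is tested by permutation: 10,000 draws of
query-sized probe sets, uniformly without replacement from the universe
of all probes on the array, recounting the overlap each time. P-values
use the plus-one estimator $p = (\#\{T_{null} \ge T_{obs}\}+1)/(B+1)$,
which is never zero and unbiased against over-claiming; the analogous
lower tail gives depletion. A result is flagged `outside_null` when the
observed count falls outside the entire null distribution — the
strongest statement $B$ draws can support. Gene-level counting (the
default for the binding-site question) counts a gene as hit when at
least one aberrant probe within ±5 kb of its TSS overlaps a binding
interval, so several probes in one promoter count once, and the null
redraws probes and recounts genes. CpG-level counting is available via
`permutation_enrichment()` directly. The sampling universe is uniform
over probes by design (matching the method being reproduced); note that
uniform sampling does not control for island-context composition, which
itself correlates with peak density — a stratified null would answer a
subtly different question and is deliberately not the default.

Coordinate conventions: array probes are 1-based positions, BED peaks
0-based half-open; a probe at position $p$ overlaps $(s, e)$ iff
$s \le p-1 < e$. Both native conventions are preserved and converted
only at the comparison point (via GenomicRanges).

**Composition vs chance.** The observed/expected class-ratio analysis
asks whether, e.g., failure classes are over-represented among observed
aberrations. "Expected by chance" is made precise as: draw sets of the
observed size uniformly without replacement from the eligible universe
(probes whose FIB and ESC states are both clear), and classify each
drawn probe by its (FIB, ESC) stratum with the aberrant iPSC state
defined as flipped relative to ESC. The ratio is observed/mean(null);
the p-value is the two-sided plus-one permutation probability. This null
is this package's own operationalisation of the idea and is stated here
because other nulls (e.g. context-stratified) are defensible.

**Concordance and cancer comparison.** Sample structure is summarised by
pairwise-complete Pearson correlation, average-linkage hierarchical
clustering of $1-r$, and PCA of mean-centred betas. Sequencing–array
concordance joins RRBS records to probes on exact (chromosome,
position), keeps CpGs with ≥ 5 reads, and correlates
methylated/total with the array beta — both assays measure absolute
methylation, so no normalisation is applied. The tumour/normal
comparison computes per-CpG tumour-minus-normal delta beta at the
aberrant CpGs and tests whether Class I (de novo methylation) CpGs are
enriched among cancer-hypermethylated CpGs ($\Delta\beta > 0.2$) with
the same permutation engine over set membership; the enrichment
statistic is this package's definition, since "enriched" alone
underdetermines a test.

## Key parameters

| parameter | default | meaning |
|-----------|---------|---------|
| `theta_diff` | 0.2 | minimum \|Δβ\| (dimensionless) for a differential call |
| `alpha` | 0.05 | FDR threshold on BH q-values |
| `theta_hyper` / `theta_hypo` | 0.7 / 0.3 | state-calling thresholds on group mean beta |
| `B` | 10000 | permutation draws; p resolution 1/(B+1) |
| `w` | 5000 | promoter half-window around the TSS (bp) |
| `min_coverage` | 5 | minimum RRBS reads per CpG |

These defaults are the standard operating point for 450K-style
aberration analysis and are exposed on every relevant function.

## The synthetic-data generator

`generate_dataset()` emulates the study design: one fibroblast batch
(profiled as 3 technical replicates so rank tests against it are
defined; configurable to 1, in which case the differential caller falls
back to a pure threshold rule and says so), 5 ESC lines, 9 Y-iPSC and
6 T-iPSC clones. Each probe carries a latent HYPER/HYPO state per group
determined by its ground-truth label (NULL, shared Class I–IV, or Y-/T-
specific Class I–IV); per-sample betas are drawn from a beta
distribution with the state mean and concentration $\kappa$
(`rbeta(μκ, (1-μ)κ)`), the standard bounded-fraction noise model. The
within-group variance of real arrays is not documented in the analysis
being reproduced, so $\kappa = 100$ (sd ≈ 0.036 at mean 0.15) is a
modelling choice, documented and configurable; state means default to
0.85/0.15 so planted states are recoverable at the 0.7/0.3 thresholds.

Default class fractions were fixed once to mirror the landscape the
method targets: shared aberrations 1.2% of probes split ~62/32/3/3
across Classes II/III/I/IV, factor-specific aberrations ~0.9% with the
Y panel biased to Class III and the T panel to Class II, and NULL
probes' fibroblast state differing from ESC with probability 0.17 — so
the simulated fibroblasts diverge from ESCs at ~17–19% of CpGs while
pooled iPSCs stay under 2%, and ESC-state probes are hypermethylated
with probability 0.55 (pluripotent genomes are predominantly
methylated).

`generate_peaks()` plants transcription-factor peaks with a controllable
coverage odds ratio for aberrant vs NULL probes (odds 1 = calibrated
null), and `simulate_rrbs()` draws binomial read counts from array
betas. Annotation (island context, gene, TSS distance) is assigned
randomly with frequencies only loosely resembling the 450K platform.

What the simulator deliberately does **not** model: intensity-level
(M/U) data, batch and chip effects, probe cross-reactivity, sex
chromosomes, copy-number artifacts, spatially correlated methylation
along the genome, and the real platform's island-context composition.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated generative model — not that any
particular biological dataset will show these effect sizes.

## Numerical choices and degenerate inputs

* Wilcoxon p-values use the exact null distribution when the combined
  sample size is ≤ 20 with no ties, otherwise the normal approximation
  with mid-ranks, tie-corrected variance and continuity correction.
  Zero rank variance (all values tied) returns p = 1.
* A probe missing in more than half of a group's samples gets an NA
  group mean; statistics exclude missing values pairwise. The probe is
  still tested if each group retains ≥ 1 value, but cannot be called
  significant without a defined Δβ.
* Permutation p-values are never 0 (plus-one), and
  `p_enrichment + p_depletion ≥ 1` because the observed value counts in
  both tails.
* Empty significant sets propagate as empty classified sets; empty
  classes yield NA ratios rather than errors.
* All generators accept a seed and restore the caller's RNG state, so
  identical seeds give byte-identical outputs (R's default Mersenne
  Twister, stable across platforms).

## Problem sizes

The bundled analysis scripts and validation suite run at desk scale,
chosen so the whole workflow re-runs in minutes on one CPU: 20,000
probes for the narrative analyses under `analysis/`, 1,000–2,500 probes
for calibration/power/concordance experiments (200, 100 and 1 replicate
respectively), and B = 10,000 permutations wherever a single test is
reported. All composition and calibration conclusions are
sampling-stable at these sizes; rerunning with a larger `n_probes`
tightens them further.

## Limitations

* Consensus clustering is simplified to deterministic average-linkage
  hierarchical clustering of $1-r$; resampling-based consensus adds
  stochastic machinery without changing conclusions on clearly separated
  groups.
* Tumour/normal comparison uses unmatched group means (TCGA-style);
  matched-pair designs are not modelled.
* Bisulfite-based betas cannot distinguish 5-methylcytosine from
  5-hydroxymethylcytosine; "methylated" here means the bisulfite-
  protected fraction.
* Region-level aggregation of adjacent CpGs, moderated tests, and batch
  correction are out of scope by design.
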