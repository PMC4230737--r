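test_that("overlap counting honors BED half-open convention", {
  ann <- probe_annotation(c("p1", "p2", "p3", "p4"), "chr1",
                          c(150, 201, 101, 100), "island")
  pk <- peak_set("chr1", 100, 200, "OCT4")
  # interval (100,200] in 1-based terms covers positions 101..200
  expect_equal(overlap_count("p1", ann, pk), 1)  # 150 inside
  expect_equal(overlap_count("p2", ann, pk), 0)  # 201 excluded (half-open)
  expect_equal(overlap_count("p3", ann, pk), 1)  # 101 is the first base in
  expect_equal(overlap_count("p4", ann, pk), 0)  # 100 is before the peak
  expect_equal(overlap_count(c("p1", "p2", "p3", "p4"), ann,
                             peak_set(character(0), integer(0),
                                      integer(0), "OCT4")), 0)
})

test_that("permutation p-values agree with the hypergeometric oracle", {
  # universe of 20 probes, 8 covered by peaks, query of 5
  ann <- simple_annotation(sprintf("p%02d", 1:20))
  covered_pos <- ann$pos[1:8]
  pk <- peak_set(rep("chr1", 8), covered_pos - 1, covered_pos, "SOX2")
  expect_equal(overlap_count(ann$probe_id, ann, pk), 8)

  B <- 10000
  for (q_idx in list(1:5, c(1, 2, 9, 10, 11), 9:13)) {
    query <- ann$probe_id[q_idx]
    res <- permutation_enrichment(query, ann$probe_id, ann, pk,
                                  B = B, seed = 42)
    obs <- res$observed_overlap
    p_exact <- stats::phyper(obs - 1, 8, 12, 5, lower.tail = FALSE)
    se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(res$p_enrichment - p_exact), 3 * se + 2 / B)
    # depletion tail too
    p_dep <- stats::phyper(obs, 8, 12, 5)
    se_d <- sqrt(p_dep * (1 - p_dep) / B)
    expect_lt(abs(res$p_depletion - p_dep), 3 * se_d + 2 / B)
    # both tails share the observed value
    expect_gte(res$p_enrichment + res$p_depletion, 1)
  }
})

test_that("saturated overlap, determinism, and input validation", {
  ann <- simple_annotation(sprintf("p%02d", 1:15))
  pk <- peak_set("chr1", min(ann$pos) - 1, max(ann$pos) + 1, "KLF4")
  res <- permutation_enrichment(ann$probe_id[1:6], ann$probe_id, ann, pk,
                                B = 500, seed = 1)
  expect_equal(res$observed_overlap, 6)
  expect_equal(res$null_mean, 6)
  expect_equal(res$p_enrichment, 1)

  r1 <- permutation_enrichment(ann$probe_id[1:4], ann$probe_id, ann, pk,
                               B = 200, seed = 9)
  r2 <- permutation_enrichment(ann$probe_id[1:4], ann$probe_id, ann, pk,
                               B = 200, seed = 9)
  expect_identical(r1$p_enrichment, r2$p_enrichment)

  expect_error(permutation_enrichment(c("p01", "zz"), ann$probe_id, ann,
                                      pk, B = 10), "subset")
  expect_error(permutation_enrichment(ann$probe_id, ann$probe_id[1:3],
                                      ann, pk, B = 10), "larger")
  # plus-one correction: p never zero even at extreme enrichment
  expect_gte(r1$p_enrichment, 1 / 201)
})

test_that("gene-level counting deduplicates genes and applies the 5 kb
           window", {
  ann <- probe_annotation(
    c("a1", "a2", "b1", "c1"), "chr1",
    c(1000, 2000, 3000, 4000), "island",
    nearest_gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
    tss_distance = c(-100, 200, 4999, 5001))
  pk <- peak_set(rep("chr1", 4), c(999, 1999, 2999, 3999),
                 c(1001, 2001, 3001, 4001), "NANOG")
  cls <- data.frame(probe_id = c("a1", "a2", "b1", "c1"),
                    class = "CLASS_I", stringsAsFactors = FALSE)
  gl <- gene_level_enrichment(cls, ann, pk, w = 5000, B = 50, seed = 1)
  # a1+a2 collapse to one gene; c1 is outside the +/-5 kb window
  expect_equal(gl$result$observed_overlap, 2)
  expect_setequal(gl$hits$gene, c("GENEA", "GENEB"))

  # idempotent under probe duplication
  gl2 <- gene_level_enrichment(rbind(cls, cls), ann, pk, w = 5000,
                               B = 50, seed = 1)
  expect_equal(gl2$result$observed_overlap, 2)
})

test_that("gene-level enrichment detects planted peak targeting", {
  cfg <- small_config(seed = 19, n_probes = 1500,
                      class_fractions = plant_fractions(SHARED_I = 0.05,
                                                        SHARED_II = 0.05))
  sim <- generate_dataset(cfg)
  pk <- generate_peaks(sim$truth, sim$annotation, "NANOG",
                       enrichment_odds = 20, seed = 3)
  d <- call_differential(sim$beta, sim$sheet, c("Y_IPSC", "T_IPSC"), "ESC")
  cls <- shared_aberrations(sim$beta, sim$sheet, d)
  gl <- gene_level_enrichment(cls, sim$annotation, pk, B = 2000, seed = 4)
  expect_true(gl$result$outside_null)
  expect_lt(gl$result$p_enrichment, 0.01)
})

test_that("island-context ratios reflect composition against the
           universe", {
  # universe uniform over the four contexts
  ann <- probe_annotation(sprintf("p%03d", 1:400), "chr1",
                          seq(1000, by = 1000, length.out = 400),
                          rep(c("island", "shore", "shelf", "open_sea"),
                              each = 100))
  island_ids <- ann$probe_id[ann$island_context == "island"]
  cls <- data.frame(probe_id = island_ids[1:50], class = "CLASS_II",
                    stringsAsFactors = FALSE)
  ic <- island_context_enrichment(cls, ann, B = 2000, seed = 2)
  r <- ic[ic$class == "CLASS_II" & ic$island_context == "island", ]
  expect_gt(r$ratio, 3.5)   # all-island set vs 1/4 expectation
  expect_lt(r$p_value, 0.01)
  # empty classes reported as missing
  expect_true(all(is.na(ic$ratio[ic$class == "CLASS_IV"])))

  # a random draw is unenriched everywhere
  set.seed(3)
  rand <- data.frame(probe_id = sample(ann$probe_id, 50),
                     class = "CLASS_I", stringsAsFactors = FALSE)
  ic2 <- island_context_enrichment(rand, ann, B = 2000, seed = 4)
  expect_true(all(ic2$p_value[ic2$class == "CLASS_I"] > 0.001))
})

test_that("TSS distance profiles bin and conserve counts", {
  ann <- probe_annotation(c("p1", "p2", "p3", "p4"), "chr1",
                          c(1, 2, 3, 4) * 1000, "shore",
                          nearest_gene = c("G1", "G2", "G3", NA),
                          tss_distance = c(0, -4000, 4000, NA))
  cls <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    scope = "shared", stringsAsFactors = FALSE)
  prof <- tss_distance_profile(cls, ann, bins = seq(-5000, 5000, 5000))
  expect_equal(sum(prof$count), 3)  # only gene-annotated probes
  # all probes at offset 0 land in one bin
  ann0 <- probe_annotation("p1", "chr1", 100, "island",
                           nearest_gene = "G", tss_distance = 0)
  prof0 <- tss_distance_profile(
    data.frame(probe_id = "p1", scope = "shared"), ann0,
    bins = seq(-5000, 5000, 1000))
  expect_equal(sum(prof0$count > 0), 1)
  # symmetric offsets give a symmetric histogram
  ann_s <- probe_annotation(sprintf("q%d", 1:4), "chr1",
                            (1:4) * 100, "shelf",
                            nearest_gene = paste0("G", 1:4),
                            tss_distance = c(-4500, -500, 500, 4500))
  prof_s <- tss_distance_profile(
    data.frame(probe_id = sprintf("q%d", 1:4), scope = "shared"),
    ann_s, bins = seq(-5000, 5000, 1000))
  expect_equal(prof_s$count, rev(prof_s$count))
})
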