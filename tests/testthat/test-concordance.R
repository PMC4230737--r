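test_that("pairwise correlation matches the textbook formula", {
  set.seed(4)
  vals <- matrix(runif(30), 10, 3,
                 dimnames = list(sprintf("cg%02d", 1:10), c("A", "B", "C")))
  cm <- pairwise_correlation_matrix(beta_matrix(vals))
  expect_equal(cm["A", "B"], pearson_oracle(vals[, 1], vals[, 2]),
               tolerance = 1e-12)
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_equal(unname(diag(cm)), rep(1, 3))

  # duplicated columns correlate at 1; constructed anti-correlation at -1
  dup <- beta_matrix(cbind(vals, D = vals[, "A"], E = 1 - vals[, "A"]))
  cm2 <- pairwise_correlation_matrix(dup)
  expect_equal(cm2["A", "D"], 1)
  expect_equal(cm2["A", "E"], -1)
})

test_that("correlation clustering separates fibroblasts, ESCs and
           iPSCs", {
  sim <- generate_dataset(small_config(seed = 15, n_probes = 1200))
  cm <- pairwise_correlation_matrix(sim$beta)
  cl <- cluster_samples(cm, k = 3)

  fib <- samples_in_group(sim$sheet, "FIB")
  esc <- samples_in_group(sim$sheet, "ESC")
  ipsc <- samples_in_group(sim$sheet, c("Y_IPSC", "T_IPSC"))
  # fibroblasts form their own tight cluster
  expect_equal(length(unique(cl[fib])), 1)
  expect_false(any(cl[fib] %in% cl[c(esc, ipsc)]))
  # ESCs do not share a cluster with iPSCs
  expect_false(any(cl[esc] %in% cl[ipsc]))

  # k = n gives singletons; sample order does not change the partition
  expect_equal(length(unique(cluster_samples(cm, ncol(sim$beta)))),
               ncol(sim$beta))
  perm <- sample(ncol(sim$beta))
  cl_p <- cluster_samples(cm[perm, perm], k = 3)[names(cl)]
  tab <- table(cl, cl_p)
  expect_equal(sum(tab > 0), 3)  # identical partition up to labels
})

test_that("PCA separates Y-iPSC, T-iPSC and ESC methylomes", {
  fr <- plant_fractions(Y_III = 0.05, T_II = 0.05, SHARED_II = 0.02)
  sim <- generate_dataset(small_config(seed = 25, n_probes = 1500,
                                       class_fractions = fr))
  keep <- samples_in_group(sim$sheet, c("ESC", "Y_IPSC", "T_IPSC"))
  sc <- pca_scores(sim$beta[, keep], 2)
  grp <- sim$sheet$group[match(rownames(sc), sim$sheet$sample_id)]
  sil <- cluster::silhouette(as.integer(factor(grp)), stats::dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0)

  # identical samples project to zero variance
  const <- beta_matrix(matrix(0.5, 10, 4,
                              dimnames = list(sprintf("cg%02d", 1:10),
                                              paste0("S", 1:4))))
  expect_equal(unname(apply(pca_scores(const, 2), 2, stats::sd)),
               c(0, 0))

  # full-rank reconstruction is lossless
  vals <- sim$beta[1:50, 1:8]
  pc <- stats::prcomp(t(vals), center = TRUE)
  rec <- t(pc$x %*% t(pc$rotation)) + rowMeans(vals)
  expect_equal(unname(rec), unname(vals), tolerance = 1e-10)
})

test_that("RRBS-array concordance joins on coordinates and applies the
           coverage filter", {
  sim <- generate_dataset(small_config(seed = 29, n_probes = 300))
  beta <- sim$beta[, "YIPSC_1"]

  # counts constructed on the representable grid give r = 1
  depth <- 10
  grid_beta <- round(beta * depth) / depth
  rr <- rrbs_profile(
    sim$annotation$chrom, sim$annotation$pos,
    as.integer(round(grid_beta * depth)), rep(depth, length(beta)))
  rep_res <- rrbs_array_concordance(rr, grid_beta, sim$annotation,
                                    min_coverage = 5)
  expect_equal(rep_res$n_shared_cpgs, length(beta))
  expect_equal(rep_res$pearson_r, 1.0)

  # every site below coverage: nothing to compare
  rr_low <- rrbs_profile(sim$annotation$chrom, sim$annotation$pos,
                         rep(1L, length(beta)), rep(2L, length(beta)))
  low <- rrbs_array_concordance(rr_low, beta, sim$annotation,
                                min_coverage = 5)
  expect_equal(low$n_shared_cpgs, 0)
  expect_true(is.na(low$pearson_r))

  # binomial resampling at depth 30 stays highly concordant
  rr_sim <- simulate_rrbs(beta, sim$annotation, depth = 30, seed = 5)
  res <- rrbs_array_concordance(rr_sim, beta, sim$annotation)
  expect_gt(res$pearson_r, 0.95)
})

test_that("cancer delta profile is antisymmetric and flags planted
           overlap", {
  sim <- generate_dataset(small_config(seed = 33, n_probes = 500))
  probes <- rownames(sim$beta)
  mu_n <- matrix(0.2, 500, 6,
                 dimnames = list(probes, paste0("N", 1:6)))
  mu_t <- matrix(0.2, 500, 6,
                 dimnames = list(probes, paste0("T", 1:6)))
  hyper_idx <- 1:60
  mu_t[hyper_idx, ] <- 0.8   # tumour-hypermethylated block
  tumor <- simulate_beta_matrix(mu_t, 200, seed = 1)
  normal <- simulate_beta_matrix(mu_n, 200, seed = 2)

  # planted overlap: iPSC Class I set = cancer-hypermethylated set
  cls <- data.frame(probe_id = probes[hyper_idx], class = "CLASS_I",
                    scope = "T_specific", stringsAsFactors = FALSE)
  prof <- cancer_delta_profile(tumor, normal, cls, B = 1000, seed = 3)
  expect_equal(prof$class1_enrichment$T_specific$p_enrichment, 1 / 1001)

  # disjoint sets of equal size flag depletion
  cls2 <- data.frame(probe_id = probes[101:160], class = "CLASS_I",
                     scope = "Y_specific", stringsAsFactors = FALSE)
  prof2 <- cancer_delta_profile(tumor, normal, cls2, B = 1000, seed = 3)
  expect_lt(prof2$class1_enrichment$Y_specific$p_depletion, 0.01)
  expect_gt(prof2$class1_enrichment$Y_specific$p_enrichment, 0.5)

  # tumor == normal: all deltas zero, nothing enriched
  prof0 <- cancer_delta_profile(tumor, tumor, cls, B = 500, seed = 4)
  expect_true(all(abs(prof0$delta) < 1e-12))
  expect_gt(prof0$class1_enrichment$T_specific$p_enrichment, 0.5)

  # antisymmetry under swapping tumor and normal
  swapped <- cancer_delta_profile(normal, tumor, cls, B = 10, seed = 5)
  expect_equal(prof$delta, -swapped$delta)
})
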