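test_that("state calling uses strict 0.7/0.3 thresholds", {
  expect_identical(call_state(0.85), "HYPER")
  expect_identical(call_state(0.15), "HYPO")
  expect_identical(call_state(0.70), "INTERMEDIATE")
  expect_identical(call_state(0.30), "INTERMEDIATE")
  expect_identical(call_state(c(0.71, 0.29, NA)),
                   c("HYPER", "HYPO", NA))
  expect_error(call_state(1.2), "\\[0, 1\\]")
})

test_that("classify_aberration matches the class definitions on all 27
           state triples", {
  states <- c("HYPER", "HYPO", "INTERMEDIATE")
  grid <- expand.grid(fib = states, esc = states, ipsc = states,
                      stringsAsFactors = FALSE)
  got <- classify_aberration(grid$fib, grid$esc, grid$ipsc)

  # independent restatement of the definitions:
  #   I:  de novo methylation    — iPSC methylated, ESC and parent not
  #   II: failed methylation     — iPSC+parent unmethylated, ESC methylated
  #   III:failed demethylation   — iPSC+parent methylated, ESC not
  #   IV: de novo demethylation  — iPSC unmethylated, ESC+parent methylated
  expected <- rep("UNCLASSIFIED", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- grid$fib[i]; e <- grid$esc[i]; p <- grid$ipsc[i]
    if (p == "HYPER" && e == "HYPO" && f == "HYPO") expected[i] <- "CLASS_I"
    if (p == "HYPO" && e == "HYPER" && f == "HYPO") expected[i] <- "CLASS_II"
    if (p == "HYPER" && e == "HYPO" && f == "HYPER") expected[i] <- "CLASS_III"
    if (p == "HYPO" && e == "HYPER" && f == "HYPER") expected[i] <- "CLASS_IV"
  }
  expect_identical(got, expected)
  # exactly 4 of the 27 triples carry a named class
  expect_equal(sum(got != "UNCLASSIFIED"), 4)
  # any triple with an INTERMEDIATE member is unclassified
  has_int <- apply(grid == "INTERMEDIATE", 1, any)
  expect_true(all(got[has_int] == "UNCLASSIFIED"))
})

test_that("shared aberrations recover planted classes", {
  cfg <- small_config(seed = 11, n_probes = 800,
                      class_fractions = plant_fractions(SHARED_II = 0.1))
  sim <- generate_dataset(cfg)
  d <- call_differential(sim$beta, sim$sheet, c("Y_IPSC", "T_IPSC"), "ESC")
  cls <- shared_aberrations(sim$beta, sim$sheet, d)
  planted <- sim$truth$probe_id[sim$truth$label == "SHARED_II"]
  recovered <- cls$probe_id[cls$class == "CLASS_II"]
  expect_gte(length(intersect(recovered, planted)) / length(planted), 0.95)
  # no recovered probe carries a wrong named class
  named <- cls[cls$class %in% c("CLASS_I", "CLASS_III", "CLASS_IV"), ]
  expect_equal(nrow(named[named$probe_id %in% planted, ]), 0)

  # no significant probes -> empty set
  d0 <- d; d0$significant <- FALSE
  expect_equal(nrow(shared_aberrations(sim$beta, sim$sheet, d0)), 0)
})

test_that("planted shared mixture composition is recovered within 5
           points", {
  fr <- plant_fractions(SHARED_I = 0.003, SHARED_II = 0.062,
                        SHARED_III = 0.032, SHARED_IV = 0.003)
  sim <- generate_dataset(small_config(seed = 23, n_probes = 4000,
                                       class_fractions = fr))
  d <- call_differential(sim$beta, sim$sheet, c("Y_IPSC", "T_IPSC"), "ESC")
  comp <- class_composition(shared_aberrations(sim$beta, sim$sheet, d))
  planted_frac <- c(CLASS_I = 0.03, CLASS_II = 0.62, CLASS_III = 0.32,
                    CLASS_IV = 0.03)
  expect_true(all(abs(comp$fraction - planted_frac[comp$class]) < 0.05))
})

test_that("factor-specific classification reports each subtype's own
           class", {
  fr <- plant_fractions(Y_III = 0.05, T_II = 0.05)
  sim <- generate_dataset(small_config(seed = 17, n_probes = 1000,
                                       class_fractions = fr))
  d <- call_differential(sim$beta, sim$sheet, "Y_IPSC", "T_IPSC")
  cls <- factor_specific_aberrations(sim$beta, sim$sheet, d)

  y3 <- sim$truth$probe_id[sim$truth$label == "Y_III"]
  ycls <- cls[cls$scope == "Y_specific" & cls$probe_id %in% y3, ]
  tcls <- cls[cls$scope == "T_specific" & cls$probe_id %in% y3, ]
  expect_gte(mean(ycls$class == "CLASS_III"), 0.95)
  expect_true(all(tcls$class == "UNCLASSIFIED"))  # T matches ESC there

  t2 <- sim$truth$probe_id[sim$truth$label == "T_II"]
  tcls2 <- cls[cls$scope == "T_specific" & cls$probe_id %in% t2, ]
  ycls2 <- cls[cls$scope == "Y_specific" & cls$probe_id %in% t2, ]
  expect_gte(mean(tcls2$class == "CLASS_II"), 0.95)
  expect_true(all(ycls2$class == "UNCLASSIFIED"))

  # no significant probes -> empty set
  d0 <- d; d0$significant <- FALSE
  expect_equal(nrow(factor_specific_aberrations(sim$beta, sim$sheet, d0)),
               0)
})

test_that("class_composition arithmetic and edge cases", {
  probes <- data.frame(class = c(rep("CLASS_II", 62), rep("CLASS_III", 30),
                                 rep("CLASS_I", 5), rep("CLASS_IV", 3),
                                 rep("UNCLASSIFIED", 10)))
  comp <- class_composition(probes)
  expect_equal(comp$fraction[comp$class == "CLASS_II"], 0.62)
  expect_equal(sum(comp$fraction), 1)
  expect_equal(nrow(class_composition(data.frame(class = character(0)))), 0)
})

test_that("observed/expected class ratios behave at the extremes", {
  # universe with equal strata: 3 FIB reps, 3 ESC, 2+2 iPSC columns
  n_per <- 60
  fib_means <- rep(c(0.1, 0.1, 0.9, 0.9), each = n_per)
  esc_means <- rep(c(0.1, 0.9, 0.1, 0.9), each = n_per)
  gm <- cbind(FIB = fib_means, ESC = esc_means,
              Y_IPSC = esc_means, T_IPSC = esc_means)
  rownames(gm) <- sprintf("cg%04d", seq_len(nrow(gm)))
  mat <- beta_matrix(plateau_matrix(gm, c(FIB = 3, ESC = 3,
                                          Y_IPSC = 2, T_IPSC = 2)))
  sheet <- sample_sheet(colnames(mat),
                        rep(c("FIB", "ESC", "Y_IPSC", "T_IPSC"),
                            c(3, 3, 2, 2)))

  # observed: all Class II probes (stratum FIB hypo / ESC hyper)
  obs <- data.frame(probe_id = rownames(gm)[(n_per + 1):(n_per + 30)],
                    class = "CLASS_II", stringsAsFactors = FALSE)
  oe <- observed_expected_class_ratio(obs, mat, sheet, n_draws = 4000,
                                      seed = 5)
  r2 <- oe$ratio[oe$class == "CLASS_II"]
  expect_gt(r2, 3.5)  # 4 strata -> ~4-fold over chance
  expect_lte(oe$p_value[oe$class == "CLASS_II"], 2 / 4001 + 1e-12)

  # observed set = whole universe -> every ratio exactly 1, p = 1
  all_obs <- data.frame(
    probe_id = rownames(gm),
    class = classify_aberration(
      call_state(fib_means), call_state(esc_means),
      ifelse(esc_means > 0.5, "HYPO", "HYPER")),
    stringsAsFactors = FALSE)
  oe_all <- observed_expected_class_ratio(all_obs, mat, sheet,
                                          n_draws = 200, seed = 6)
  expect_equal(oe_all$ratio, rep(1, 4))
  expect_equal(oe_all$p_value, rep(1, 4))

  # a uniformly drawn observed set is unremarkable
  set.seed(8)
  rand <- all_obs[sample(nrow(all_obs), 40), ]
  oe_rand <- observed_expected_class_ratio(rand, mat, sheet,
                                           n_draws = 2000, seed = 7)
  expect_true(all(oe_rand$p_value > 0.001))
})
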