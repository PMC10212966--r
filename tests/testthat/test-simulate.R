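test_that("sample_proteome_model draws valid, reproducible proteomes", {
  m <- sample_proteome_model(2000, seed = 0, tm_mean = 52.5, tm_sd = 2,
                             plateau_max = 0.2)
  expect_length(m$protein_ids, 2000)
  expect_false(anyDuplicated(m$protein_ids) > 0)
  expect_true(all(m$tm >= 40 & m$tm <= 70))
  expect_true(all(m$slope > 0))
  expect_true(all(m$plateau >= 0 & m$plateau < 0.2))
  expect_true(all(m$base_abundance > 0))
  # abundance spans >= 3 orders of magnitude
  expect_gte(log10(max(m$base_abundance) / min(m$base_abundance)), 3)
  # bit-identical under the same seed
  m2 <- sample_proteome_model(2000, seed = 7)
  m3 <- sample_proteome_model(2000, seed = 7)
  expect_identical(m2, m3)
  expect_error(sample_proteome_model(0), "positive")
  expect_error(sample_proteome_model(10, tm_sd = 0), "positive")
})

test_that("Tm sample mean matches the target at large n", {
  m <- sample_proteome_model(10000, seed = 3, tm_mean = 52.5, tm_sd = 2)
  expect_equal(mean(m$tm), 52.5, tolerance = 0.1 / 52.5)
})

test_that("apply_treatment_effect labels and effect moments", {
  m <- sample_proteome_model(2000, seed = 0)
  # no effects at all
  e0 <- apply_treatment_effect(m, frac_stabilized = 0, frac_abundance = 0)
  expect_true(all(e0$labels == "null"))
  expect_true(all(e0$delta_tm == 0))
  expect_true(all(e0$log2_abundance_effect == 0))
  # exact counts under the sampling rule
  e <- apply_treatment_effect(m, frac_stabilized = 0.05, mean_delta_tm = 1.5,
                              sd_delta_tm = 0.5, frac_abundance = 0.05,
                              seed = 4)
  expect_identical(sum(e$labels == "substrate_stabilized"), 100L)
  expect_identical(sum(e$labels == "abundance_changed"), 100L)
  # substrates and abundance-changed proteins are disjoint
  expect_true(all(e$delta_tm[e$labels == "abundance_changed"] == 0))
  # mean of the nonzero shifts near the target
  expect_equal(mean(e$delta_tm[e$delta_tm != 0]), 1.5, tolerance = 0.15 / 1.5)
  # ground truth recoverable and aligned
  expect_identical(e$ground_truth$protein_id, m$protein_ids)
  expect_identical(e$ground_truth$label, e$labels)
  expect_error(apply_treatment_effect(m, frac_stabilized = 1.2), "\\[0, 1\\]")
  expect_error(apply_treatment_effect(m, frac_stabilized = 0.6,
                                      frac_abundance = 0.6), "disjoint")
})

test_that("simulate_pisa_dataset reproduces the generative arithmetic", {
  m <- sample_proteome_model(50, seed = 1)
  # zero noise, zero effects: every log2 ratio is exactly 0
  e0 <- apply_treatment_effect(m, 0, 0, 0, 0, 0, seed = 1)
  d0 <- simulate_pisa_dataset(m, e0, experiment_design(noise_cv = 0, seed = 1))
  sta <- d0$stability
  lfc <- rowMeans(sta[, grepl("^treated", colnames(sta))]) -
    rowMeans(sta[, grepl("^control", colnames(sta))])
  expect_equal(unname(lfc), rep(0, 50))
  expect_true(all(is.finite(d0$stability)) && all(is.finite(d0$abundance)))

  # one protein with delta_tm = +2 at known curve: ratio equals the
  # brute-force window-mean ratio of the two logistics
  m1 <- sample_proteome_model(3, seed = 2)
  m1$tm[1] <- 53; m1$slope[1] <- 1; m1$plateau[1] <- 0.1
  e1 <- apply_treatment_effect(m1, 0, 0, 0, 0, 0, seed = 1)
  e1$delta_tm[1] <- 2
  d1 <- simulate_pisa_dataset(m1, e1, experiment_design(noise_cv = 0, seed = 1))
  lfc1 <- mean(d1$stability[1, 4:6]) - mean(d1$stability[1, 1:3])
  expected <- log2(mean(oracle_logistic(55, 1, 0.1, 51:56)) /
                     mean(oracle_logistic(53, 1, 0.1, 51:56)))
  expect_equal(lfc1, expected, tolerance = 1e-10)

  # a pure abundance effect propagates equally into both channels
  e2 <- apply_treatment_effect(m1, 0, 0, 0, 0, 0, seed = 1)
  e2$log2_abundance_effect[2] <- -0.5
  d2 <- simulate_pisa_dataset(m1, e2, experiment_design(noise_cv = 0, seed = 1))
  expect_equal(mean(d2$stability[2, 4:6]) - mean(d2$stability[2, 1:3]), -0.5)
  expect_equal(mean(d2$abundance[2, 4:6]) - mean(d2$abundance[2, 1:3]), -0.5)
})

test_that("simulate_pisa_dataset column dialect and determinism", {
  m <- sample_proteome_model(20, seed = 5)
  e <- apply_treatment_effect(m, 0.1, 1, 0.5, 0.1, -0.5, seed = 5)
  des <- experiment_design(n_reps_control = 3, n_reps_treated = 2,
                           noise_cv = 0.08, seed = 6)
  d <- simulate_pisa_dataset(m, e, des)
  expect_identical(colnames(d$stability),
                   c(sprintf("control_stability_rep%d", 1:3),
                     sprintf("treated_stability_rep%d", 1:2)))
  expect_identical(colnames(d$abundance),
                   c(sprintf("control_abundance_rep%d", 1:3),
                     sprintf("treated_abundance_rep%d", 1:2)))
  d2 <- simulate_pisa_dataset(m, e, des)
  expect_identical(d, d2)
  expect_error(experiment_design(temperatures = 51), ">= 2")
  expect_error(experiment_design(n_reps_control = 1), ">= 2")
})

test_that("simulate_gradient_dataset geometry and cardinality", {
  p0 <- melt_params(53, 1, 0.1)
  p1 <- melt_params(55, 1, 0.1)
  # identical params, zero noise: the two condition curves coincide
  tab0 <- simulate_gradient_dataset(list(x = list(control = p0, treated = p0)),
                                    noise_cv = 0, seed = 1)
  ctrl <- tab0[tab0$condition == "control", ]
  trt <- tab0[tab0$condition == "treated", ]
  expect_equal(ctrl$quantity, trt$quantity)
  # +2 degC shift: treated soluble fraction dominates everywhere
  tab2 <- simulate_gradient_dataset(list(x = list(control = p0, treated = p1)),
                                    noise_cv = 0, seed = 1)
  ag <- aggregate(quantity ~ condition + temperature_c, tab2, mean)
  wide <- reshape(ag, idvar = "temperature_c", timevar = "condition",
                  direction = "wide")
  expect_true(all(wide$quantity.treated >= wide$quantity.control))
  # 2 conditions x 5 temperatures x 2 replicates = 20 rows per target
  expect_identical(nrow(tab2), 20L)
  # carrier proteins decrease with temperature
  carrier <- sample_proteome_model(5, seed = 2)
  tabc <- simulate_gradient_dataset(list(x = list(control = p0, treated = p0)),
                                    carrier = carrier, noise_cv = 0, seed = 1)
  for (id in carrier$protein_ids) {
    q <- tabc[tabc$protein_id == id & tabc$condition == "control" &
                tabc$replicate == 1, ]
    expect_true(all(diff(q$quantity[order(q$temperature_c)]) < 0))
  }
  expect_error(simulate_gradient_dataset(
    list(x = list(control = p0, treated = p0)), temperatures = c(50, 55)),
    ">= 3")
})

test_that("simulate_methyl_peptide_table follows the occupancy arithmetic", {
  occ <- matrix(c(0, 0.8), 1, dimnames = list("s1", c("ref", "test")))
  tab <- simulate_methyl_peptide_table(occ, noise_cv = 0, seed = 1)
  u_ref <- tab$quantity[tab$condition == "ref" & tab$form == "unmodified"]
  u_test <- tab$quantity[tab$condition == "test" & tab$form == "unmodified"]
  expect_equal(u_test / u_ref, 0.2)
  m_ref <- tab$quantity[tab$condition == "ref" & tab$form != "unmodified"]
  expect_true(all(m_ref == 0))
  # zero occupancy in both conditions: unmodified ratio = loading ratio
  occ0 <- matrix(c(0, 0), 1, dimnames = list("s1", c("ref", "test")))
  tab0 <- simulate_methyl_peptide_table(
    occ0, loading = c(ref = 1, test = 2), noise_cv = 0, seed = 1)
  expect_equal(tab0$quantity[tab0$condition == "test" &
                               tab0$form == "unmodified"] /
                 tab0$quantity[tab0$condition == "ref" &
                                 tab0$form == "unmodified"], 2)
  # determinism
  expect_identical(simulate_methyl_peptide_table(occ, noise_cv = 0.1, seed = 9),
                   simulate_methyl_peptide_table(occ, noise_cv = 0.1, seed = 9))
  expect_error(simulate_methyl_peptide_table(matrix(1.2)), "\\[0, 1\\]")
})
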