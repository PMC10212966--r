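make_matrix <- function(n = 200, seed = 1, reps = 3) {
  set.seed(seed)
  cols <- c(sprintf("control_stability_rep%d", seq_len(reps)),
            sprintf("treated_stability_rep%d", seq_len(reps)))
  matrix(rnorm(n * 2 * reps, 20, 1), n, 2 * reps,
         dimnames = list(sprintf("P%04d", seq_len(n)), cols))
}

test_that("normalize_log_intensities is a fixed point on aligned columns", {
  m <- make_matrix()
  same <- m[, rep(1, 6)]
  colnames(same) <- colnames(m)
  out <- normalize_log_intensities(same)
  expect_equal(out, same, tolerance = 1e-12)
})

test_that("normalize_log_intensities removes a constant column offset", {
  m <- make_matrix()
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 1.0
  out <- normalize_log_intensities(shifted)
  meds <- apply(out, 2, median)
  expect_lt(max(meds) - min(meds), 1e-9)
  # the offset column is back near the original
  expect_equal(median(out[, 2]), median(m[, 2]), tolerance = 0.1)
})

test_that("normalize_log_intensities removes intensity-dependent bow", {
  m <- make_matrix(n = 1000, seed = 2)
  rm_ <- rowMeans(m)
  bowed <- m
  bowed[, 1] <- bowed[, 1] + 0.1 * (rm_ - mean(rm_))
  out <- normalize_log_intensities(bowed)
  dev <- out[, 1] - rowMeans(out)
  trend <- coef(lm(dev ~ rm_))[[2]]
  expect_lt(abs(trend), 0.01)
})

test_that("normalize_log_intensities rejects incomplete matrices", {
  m <- make_matrix(n = 10)
  m[1, 1] <- NA
  expect_error(normalize_log_intensities(m), "complete")
})

test_that("moderated t with prior_df 0 equals the ordinary pooled t", {
  m <- make_matrix(n = 1000, seed = 3)
  res <- moderated_t_test(m, 4:6, 1:3, prior_df = 0)
  tt <- apply(m, 1, function(v)
    t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  expect_lt(max(abs(res$t - tt)), 1e-9)
  # hand case: a = (1.0, 1.2, 1.1), b = (0.1, 0.2, 0.3) -> t ~ 11.02 on 4 df
  one <- matrix(c(0.1, 0.2, 0.3, 1.0, 1.2, 1.1), 1)
  r1 <- moderated_t_test(one, 4:6, 1:3, prior_df = 0)
  expect_equal(r1$t, 11.0227, tolerance = 1e-4)
  expect_equal(r1$df_total, 4)
})

test_that("identical per-protein variances collapse to a common-variance statistic", {
  # rows share one variance exactly: the log-variances have zero spread, the
  # prior df estimate is infinite and every posterior variance is the common
  # prior, so t is proportional to the mean difference for every protein
  set.seed(4)
  base <- rnorm(6)
  m <- t(vapply(1:50, function(i) base + rnorm(1), numeric(6)))
  colnames(m) <- c(sprintf("c_rep%d", 1:3), sprintf("t_rep%d", 1:3))
  res <- moderated_t_test(m, 4:6, 1:3)
  pr <- attr(res, "shrinkage")
  expect_true(is.infinite(pr$prior_df))
  ratio <- res$t / res$log2fc
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("moderated t shrinkage limits behave as prior_df varies", {
  m <- make_matrix(n = 300, seed = 5)
  r_inf <- moderated_t_test(m, 4:6, 1:3, prior_df = Inf)
  # common variance: |t| proportional to |log2fc|
  ord1 <- order(abs(r_inf$log2fc))
  ord2 <- order(abs(r_inf$t))
  expect_identical(ord1, ord2)
  expect_true(is.infinite(r_inf$df_total[1]))
  # equal group means give t = 0, p = 1
  flat <- matrix(rep(c(1, 2, 3), 2), 1)
  rf <- moderated_t_test(flat, 4:6, 1:3, prior_df = 0)
  expect_equal(rf$t, 0)
  expect_equal(rf$p, 1)
  expect_error(moderated_t_test(m, 4:5, 6), ">= 2")
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  m <- make_matrix(n = 500, seed = 6)
  # heterogeneous variances so shrinkage is non-trivial
  set.seed(7)
  m <- m * exp(rnorm(nrow(m), 0, 0.5))
  res <- moderated_t_test(m, 4:6, 1:3)
  design <- cbind(1, grepl("^treated", colnames(m)))
  fit <- limma::eBayes(limma::lmFit(m, design))
  pr <- attr(res, "shrinkage")
  expect_equal(pr$prior_df, fit$df.prior, tolerance = 0.05)
  expect_equal(pr$prior_var, fit$s2.prior, tolerance = 0.01)
  expect_lt(max(abs(res$t - fit$t[, 2])), 0.02)
  expect_lt(max(abs(res$p - fit$p.value[, 2])), 0.005)
})

test_that("null p-values are uniform on the simulated global null", {
  m <- sample_proteome_model(2000, seed = 0)
  e0 <- apply_treatment_effect(m, 0, 0, 0, 0, 0, seed = 0)
  d <- simulate_pisa_dataset(m, e0, experiment_design(noise_cv = 0.08,
                                                      seed = 0))
  r <- diff_channel(d$stability)
  ks <- suppressWarnings(ks.test(r$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("unbalanced 3v2 design runs and controls type I", {
  m <- sample_proteome_model(1000, seed = 1)
  e0 <- apply_treatment_effect(m, 0, 0, 0, 0, 0, seed = 1)
  d <- simulate_pisa_dataset(m, e0, experiment_design(
    n_reps_control = 3, n_reps_treated = 2, noise_cv = 0.08, seed = 1))
  r <- diff_channel(d$stability)
  expect_lt(mean(r$p < 0.01), 0.03)
  expect_true(all(r$regulated == "none" | abs(r$log2fc) > 0.1))
})

test_that("bh_adjust reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in p rank and invariant to input order
  set.seed(8)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("call_regulated applies the standard thresholds", {
  expect_identical(call_regulated(0.2, 0.005), "up")
  expect_identical(call_regulated(0.05, 0.001), "none")
  expect_identical(call_regulated(-0.3, 0.02), "none")
  expect_identical(call_regulated(-0.3, 0.005), "down")
  expect_identical(call_regulated(c(0.2, -0.2, 0.0), c(0.001, 0.001, 0.001)),
                   c("up", "down", "none"))
  expect_error(call_regulated(0.2, 0.005, fc_threshold = -1), "positive")
})

test_that("joint classification separates stability from expression", {
  expect_identical(joint_stability_abundance_classify(
    "up", "none", 0.3, 0.0), "stability_only")
  expect_identical(joint_stability_abundance_classify(
    "none", "down", 0.0, -0.4), "abundance_only")
  # both down and close: abundance-driven
  expect_identical(joint_stability_abundance_classify(
    "down", "down", -0.4, -0.38), "concordant_both")
  expect_identical(joint_stability_abundance_classify(
    "up", "down", 0.4, -0.4), "discordant")
  expect_identical(joint_stability_abundance_classify(
    "up", "up", 0.5, 0.15), "discordant")
  expect_identical(joint_stability_abundance_classify(
    "none", "none", 0.0, 0.0), "none")
  expect_error(joint_stability_abundance_classify(
    c("up", "up"), "up", 0.1, 0.1), "same proteins")
})

test_that("abundance-only proteins are never called stability_only without noise", {
  m <- sample_proteome_model(300, seed = 2)
  e <- apply_treatment_effect(m, 0, 0, 0.5, frac_abundance = 0.2,
                              mean_log2_abund = -0.5, seed = 2)
  d <- simulate_pisa_dataset(m, e, experiment_design(noise_cv = 0, seed = 2))
  wf <- suppressWarnings(run_pisa_workflow(list(t = d), normalize = FALSE))
  res <- wf$results$t
  ab_ids <- e$ground_truth$protein_id[e$ground_truth$label == "abundance_changed"]
  expect_false(any(res$joint_class[res$protein_id %in% ab_ids] ==
                     "stability_only"))
})
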