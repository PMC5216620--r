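test_that("config validation rejects malformed worlds", {
  expect_error(sim_config(n_older = 2), class = "connage_config_error")
  expect_error(sim_config(age_range_older = c(76, 51)),
               class = "connage_config_error")
  expect_error(sim_config(base_within_network_r = 1),
               class = "connage_config_error")
  expect_error(sim_config(node_labels = c(SM_NODES <- c("M1.L"), "Null.1")),
               class = "connage_config_error")
})

test_that("target correlation encodes the linear age rule exactly", {
  # hand evaluation: base 0.5, slope -0.01/yr, age 70, min 50 -> 0.30
  cfg <- sim_config(age_range_older = c(50, 76), base_within_network_r = 0.5,
                    insula_decline_slope = -0.01, parietal_increase_delta = 0,
                    subject_jitter_sd = 0)
  R <- build_target_correlation(list(group = "older", age = 70), cfg)
  for (a in c("Ins.L", "Ins.R")) for (b in c("M1.L", "M1.R", "S1.L", "S1.R"))
    expect_equal(R[a, b], 0.30)
  # zero-offset case: at the range minimum the insula edges equal the base
  R0 <- build_target_correlation(list(group = "older", age = 50), cfg)
  expect_equal(R0["Ins.L", "M1.L"], 0.5)
  # no-effect case: older and younger matrices identical
  cfg0 <- sim_config(insula_decline_slope = 0, parietal_increase_delta = 0)
  expect_identical(
    build_target_correlation(list(group = "older", age = 60), cfg0),
    build_target_correlation(list(group = "younger", age = 22), cfg0))
})

test_that("target matrices are valid correlation matrices", {
  cfg <- sim_config()
  for (age in c(51, 63, 76)) {
    R <- build_target_correlation(list(group = "older", age = age), cfg,
                                  base_shift = 0.2)
    expect_true(isSymmetric(R))
    expect_equal(unname(diag(R)), rep(1, nrow(R)))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_true(all(abs(R[upper.tri(R)]) < 1))
    # null nodes stay uncorrelated
    expect_equal(unname(R["Null.1", "M1.L"]), 0)
    expect_equal(unname(R["Null.2", "Null.3"]), 0)
  }
})

test_that("positive-definite repair clips and rescales", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)  # indefinite
  M <- repair_correlation(R)
  expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(M), rep(1, 3))
  # an already-PD matrix is returned unchanged
  R2 <- diag(3)
  expect_identical(repair_correlation(R2), R2)
})

test_that("simulate_cohort is deterministic and has the right shape", {
  cfg <- sim_config(rng_seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$series[["older_001"]]$values,
                   b$series[["older_001"]]$values)
  expect_identical(a$motion, b$motion)
  # cohort of 52 + 51 subjects
  expect_equal(nrow(a$cohort), 103)
  expect_equal(sum(a$cohort$group == "older"), 52)
  expect_equal(dim(a$series[[1]]$values),
               c(250, length(cfg$node_labels)))
  rng_o <- range(a$cohort$age[a$cohort$group == "older"])
  expect_true(rng_o[1] >= 51 && rng_o[2] <= 76)
  expect_true(all(a$cohort$gmv > 0))
})

test_that("empirical correlations converge to their targets", {
  # sampling-error bound: Fisher-z se = 1/sqrt(T-3) ~ 0.01 at T = 10000
  cfg <- sim_config(n_older = 3, n_younger = 3, n_timepoints = 10000,
                    base_within_network_r = 0.5, insula_decline_slope = 0,
                    parietal_increase_delta = 0, subject_jitter_sd = 0,
                    rng_seed = 21)
  sim <- simulate_cohort(cfg)
  x <- sim$series[[1]]$values
  expect_lt(abs(cor(x[, "M1.L"], x[, "S1.R"]) - 0.5), 0.03)
  expect_lt(abs(cor(x[, "M1.L"], x[, "Null.1"])), 0.03)
})

test_that("covariance fidelity: mean empirical-vs-target bias is small", {
  cfg <- sim_config(n_older = 25, n_younger = 25, n_timepoints = 2000,
                    rng_seed = 31)
  sim <- simulate_cohort(cfg)
  err <- vapply(sim$cohort$subject_id, function(id) {
    emp <- cor(sim$series[[id]]$values)
    tgt <- sim$truth$targets[[id]]
    emp["Ins.L", "M1.L"] - tgt["Ins.L", "M1.L"]
  }, 0)
  expect_lt(abs(mean(err)), 0.02)
})

test_that("age-connectivity effect is recoverable at study scale", {
  # with slope -0.01/yr and T = 250 the insula-edge z correlates negatively
  # with age within the older group in nearly all replicate cohorts
  neg <- 0
  reps <- 25  # scaled from 100 for runtime; binomial bound unchanged
  for (r in seq_len(reps)) {
    cfg <- sim_config(insula_decline_slope = -0.01, rng_seed = 100 + r,
                      n_younger = 3)
    sim <- simulate_cohort(cfg)
    older <- sim$cohort[sim$cohort$group == "older", ]
    z <- vapply(older$subject_id, function(id) {
      x <- sim$series[[id]]$values
      atanh(cor(x[, "Ins.L"], x[, "M1.L"]))
    }, 0)
    if (cor(older$age, z) < 0) neg <- neg + 1
  }
  expect_gte(neg / reps, 0.95)
})

test_that("motion traces respect the high-motion contract", {
  # disabled case: no trace may trip the strict thresholds
  cfg0 <- small_config(high_motion_fraction = 0)
  set.seed(5)
  for (i in 1:50) {
    m <- simulate_motion(cfg0)
    expect_lte(max(abs(m)), 1)
  }
  # saturated case: every subject flagged downstream
  cfg1 <- small_config(seed = 2, high_motion_fraction = 1)
  sim <- simulate_cohort(cfg1)
  exc <- apply_exclusion(sim$cohort, sim$motion)
  expect_true(all(exc$qc$excluded))
  # degenerate noise: constant trace, FD 0 downstream
  cfgz <- small_config(motion_step_sd = 0)
  set.seed(1)
  mz <- simulate_motion(cfgz)
  expect_equal(unname(compute_fd(mz)),
               c(0, 0))
})

test_that("planted-feature table has the prescribed population structure", {
  sim <- simulate_feature_table(5000, 5, -0.6, rng_seed = 3)
  expect_lt(abs(cor(sim$X[, 1], sim$age) + 0.6), 0.05)
  expect_lt(max(abs(cor(sim$X[, -1], sim$age))), 0.06)
})
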