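test_that("telegraph generator with zero rates stays in the bound well", {
  cfg <- latch_sim_config(n_frames = 2000L, dt = 0.5, switch_rate_on = 0,
                          switch_rate_off = 0, seed = 5)
  sim <- gen_latch_trajectory(cfg)
  expect_true(all(sim$truth$state == "bound"))
  d <- vapply(sim$trajectory$frames, function(fr)
    sqrt(sum((fr[2, ] - fr[1, ])^2)), numeric(1))
  expect_lt(abs(mean(d) - cfg$bound_mean),
            3 * cfg$well_sd / sqrt(cfg$n_frames))
})

test_that("symmetric switching rates give half released occupancy", {
  # tau_c = 1/(k_on + k_off) = 50 ns; with dt = 10 ns and 50,000 frames the
  # occupancy estimator's SD is ~sqrt(2 * 0.25 * tau_c / T) ~ 0.007
  cfg <- latch_sim_config(n_frames = 50000L, dt = 10,
                          switch_rate_on = 0.01, switch_rate_off = 0.01,
                          seed = 2)
  sim <- gen_latch_trajectory(cfg)
  expect_lt(abs(sim$occupancy_released - 0.5), 0.02)
})

test_that("telegraph occupancy converges to the rate-implied stationary value", {
  for (rates in list(c(0.02, 0.02), c(0.03, 0.01), c(0.01, 0.03))) {
    cfg <- latch_sim_config(n_frames = 40000L, dt = 10,
                            switch_rate_on = rates[1],
                            switch_rate_off = rates[2], seed = 7)
    sim <- gen_latch_trajectory(cfg)
    stat_rel <- rates[2] / (rates[1] + rates[2])  # off-rate feeds released
    tau <- 1 / sum(rates)
    sd_occ <- sqrt(2 * stat_rel * (1 - stat_rel) * tau /
                     (cfg$n_frames * cfg$dt))
    expect_lt(abs(sim$occupancy_released - stat_rel), 4 * sd_occ + 0.005)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- latch_sim_config(n_frames = 500L, seed = 9)
  s1 <- gen_latch_trajectory(cfg); s2 <- gen_latch_trajectory(cfg)
  expect_identical(s1$trajectory$frames, s2$trajectory$frames)
  ccfg <- correlation_sim_config(diag(4), n_frames = 50, seed = 9)
  expect_identical(gen_correlated_trajectory(ccfg)$frames,
                   gen_correlated_trajectory(ccfg)$frames)
  mcfg <- bilayer_sim_config(total_lipids = 70, n_frames = 3, seed = 9)
  expect_identical(gen_membrane_system(mcfg)$trajectory$frames,
                   gen_membrane_system(mcfg)$trajectory$frames)
  kcfg <- catalog_sim_config(n_samples = 200,
                             position_frequencies = c("545" = 0.1, "1047" = 0.2),
                             seed = 9)
  expect_identical(gen_mutation_catalog(kcfg)$catalog,
                   gen_mutation_catalog(kcfg)$catalog)
  expect_identical(gen_pocket_records(10, seed = 9),
                   gen_pocket_records(10, seed = 9))
})

test_that("identity correlation target yields near-zero off-diagonals", {
  cfg <- correlation_sim_config(diag(6), n_frames = 20000L, seed = 3)
  traj <- gen_correlated_trajectory(cfg)
  C <- correlation_matrix(traj)$C
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.03)
})

test_that("perfectly correlated and anticorrelated targets are planted exactly", {
  C <- diag(3); C[1, 2] <- C[2, 1] <- 1
  traj <- gen_correlated_trajectory(correlation_sim_config(C, n_frames = 500,
                                                           seed = 4))
  d1 <- vapply(traj$frames, function(fr) fr[1, 1], numeric(1))
  d2 <- vapply(traj$frames, function(fr) fr[2, 1], numeric(1))
  expect_gt(cor(d1 - mean(d1), d2 - mean(d2)), 1 - 1e-10)
  Cm <- diag(3); Cm[1, 2] <- Cm[2, 1] <- -1
  trajm <- gen_correlated_trajectory(correlation_sim_config(Cm, n_frames = 500,
                                                            seed = 4))
  e1 <- vapply(trajm$frames, function(fr) fr[1, 1], numeric(1))
  e2 <- vapply(trajm$frames, function(fr) fr[2, 1], numeric(1))
  expect_lt(cor(e1, e2), -0.99)
})

test_that("non-PSD correlation targets are rejected with the eigenvalue", {
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(correlation_sim_config(C), "eigenvalue")
})

test_that("sample correlation converges to the target as frames grow", {
  C <- diag(4); C[1, 2] <- C[2, 1] <- 0.6; C[3, 4] <- C[4, 3] <- -0.4
  errs <- vapply(c(500L, 8000L), function(nf) {
    traj <- gen_correlated_trajectory(correlation_sim_config(C, n_frames = nf,
                                                             seed = 12))
    max(abs(correlation_matrix(traj)$C - C))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)
})

test_that("bilayer composition arithmetic is exact", {
  mem <- gen_membrane_system(bilayer_sim_config(total_lipids = 700,
                                                molar_ratio = c(28, 6, 1),
                                                n_frames = 1, seed = 1))
  expect_equal(unname(mem$composition[c("DOPC", "DOPS", "PIP2")]),
               c(560L, 120L, 20L))
  expect_equal(ratio_counts(3, c(1, 1, 1)), c(1L, 1L, 1L))
  expect_equal(sum(ratio_counts(100, c(28, 6, 1))), 100L)
})

test_that("null mutation catalog is calibrated: Fisher CIs cover OR = 1", {
  pos <- seq(100L, 210L, by = 10L)   # 12 positions, 66 pairs
  cfg <- catalog_sim_config(
    n_samples = 600L,
    position_frequencies = setNames(rep(0.05, length(pos)), pos),
    seed = 21)
  ind <- gen_mutation_catalog(cfg)$indicator
  pairs <- t(combn(ncol(ind), 2))
  covered <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- sum(ind[, pairs[k, 1]] & ind[, pairs[k, 2]])
    b <- sum(ind[, pairs[k, 1]]) - a
    c_ <- sum(ind[, pairs[k, 2]]) - a
    d <- nrow(ind) - a - b - c_
    ci <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$conf.int
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("planted exclusive pair with strength 1 never co-occurs", {
  cfg <- catalog_sim_config(
    n_samples = 3000L,
    position_frequencies = c("545" = 0.2, "1047" = 0.2),
    planted_doublets = data.frame(posA = 545, posB = 1047,
                                  joint_mode = "exclusive", strength = 1),
    seed = 8)
  gen <- gen_mutation_catalog(cfg)
  expect_equal(sum(gen$indicator[, "545"] & gen$indicator[, "1047"]), 0L)
  expect_equal(gen$truth$p11, 0)
})

test_that("pocket record generator straddles every screening boundary", {
  expect_equal(nrow(gen_pocket_records(0)), 0L)
  rec <- gen_pocket_records(8, seed = 2)
  expect_equal(nrow(rec), 8L)
  expect_true(any(rec$druggability_probability == 0.5))
  expect_true(any(rec$druggability_probability > 0.5))
  expect_true(any(rec$druggability_probability < 0.5))
  nres <- lengths(strsplit(rec$lining_residues, ";"))
  expect_true(any(nres == 13) && any(nres >= 14))
})
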