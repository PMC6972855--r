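test_that("the parameter pool reproduces the target zero-profile summaries", {
  pool <- synthetic_parameter_pool(5000, seed = 1)
  # mean biological-zero proportion calibrated near 0.80
  expect_gt(mean(pool$p_bpmv), 0.75)
  expect_lt(mean(pool$p_bpmv), 0.85)
  expect_lt(min(pool$p_bpmv), 0.01)
  expect_gt(max(pool$p_bpmv), 0.99)
  # induced technical-zero fraction: total zero probability minus the
  # biological point mass; pool mean between 0.5% and 5%
  tpmv <- pmv_probability(pool$p_bpmv, pool$mu, pool$sigma, pool$lambda) -
    pool$p_bpmv
  expect_gt(mean(tpmv), 0.005)
  expect_lt(mean(tpmv), 0.05)
  # means never fall below the detection limit (pool exclusion rule)
  expect_true(all(pool$mu >= pool$lambda))
  # determinism
  expect_identical(pool, synthetic_parameter_pool(5000, seed = 1))
})

test_that("feature simulation follows the generative mixture", {
  set.seed(2)
  expect_true(all(simulate_feature(1, 1, 1, 0, 50) == 0))
  # no zeros, no censoring: log-sample mean near mu
  y <- simulate_feature(2.5, 0, 1, -Inf, 1e5)
  expect_lt(abs(mean(log(y)) - 2.5), 3 / sqrt(1e5))
  # censoring at the mean: half the draws fall below
  y <- simulate_feature(2.5, 0, 1, 2.5, 1e5)
  expect_lt(abs(mean(y == 0) - 0.5), 3 * 0.5 / sqrt(1e5))
})

test_that("simulated datasets carry the configured differential truth", {
  pool <- synthetic_parameter_pool(2000, seed = 5)
  cfg <- scenario_config(n_features = 5000, n_per_group = 20,
    n_replicates = 1, seed = 6)
  sim <- simulate_dataset(pool, cfg, rep = 1)
  expect_identical(sum(sim$truth$is_de), 500L)
  expect_identical(sum(sim$truth$direction == 1L), 250L)
  expect_identical(sum(sim$truth$direction == -1L), 250L)
  expect_equal(sim$truth$mu_case[sim$truth$direction == 1][1] -
    sim$truth$mu_control[sim$truth$direction == 1][1], log(2))

  # down-shifted features suffer more case-group censoring than up-shifted
  tpmv_case <- pmv_probability(sim$truth$p_case, sim$truth$mu_case,
    sim$truth$sigma, sim$truth$lambda) - sim$truth$p_case
  expect_gt(mean(tpmv_case[sim$truth$direction == -1]),
    mean(tpmv_case[sim$truth$direction == 1]))

  # control-group zero fraction tracks the pool mean
  zero_frac <- rowMeans(sim$matrix[, 1:20] == 0)
  total_zero_prob <- pmv_probability(sim$truth$p_control,
    sim$truth$mu_control, sim$truth$sigma, sim$truth$lambda)
  expect_lt(abs(mean(zero_frac) - mean(total_zero_prob)), 0.02)

  # null configuration
  cfg0 <- scenario_config(n_features = 50, de_fraction = 0,
    n_per_group = 10, n_replicates = 1, seed = 6)
  sim0 <- simulate_dataset(pool, cfg0, rep = 1)
  expect_false(any(sim0$truth$is_de))
})

test_that("proportion effects shift the zero-inflation logit", {
  pool <- synthetic_parameter_pool(500, seed = 7)
  cfg <- scenario_config(n_features = 200, n_per_group = 10,
    n_replicates = 1, seed = 8, effect_target = "proportion")
  sim <- simulate_dataset(pool, cfg, rep = 1)
  de <- sim$truth[sim$truth$is_de, ]
  expect_true(all(abs(abs(qlogis(de$p_case) - qlogis(de$p_control)) -
    log(2)) < 1e-9))
  expect_true(all(sim$truth$mu_case == sim$truth$mu_control))
})

test_that("ranking and FDR metrics follow their definitions", {
  truth <- tibble::tibble(feature_id = paste0("f", 1:10),
    is_de = c(rep(TRUE, 3), rep(FALSE, 7)))
  res <- tibble::tibble(feature_id = paste0("f", 1:10),
    p_value = seq(0.001, 0.5, length.out = 10),
    lrt_stat = 10:1,
    q_value = c(0.004, 0.009, 0.04, rep(0.6, 7)))
  tc <- tpr_curve(res, truth, max_k = 5)
  expect_equal(tc$tpr[1:3], c(1, 1, 1))
  expect_equal(tc$tpr[5], 3 / 5)
  fdr <- observed_fdr(res, truth, 0.05)
  expect_identical(fdr$tp, 3L)
  expect_identical(fdr$fp, 0L)
  expect_equal(fdr$observed_fdr, 0)
  # none selected: defined as zero, flagged
  fdr0 <- observed_fdr(res, truth, 0.001)
  expect_true(fdr0$empty_selection)
  expect_equal(fdr0$observed_fdr, 0)
  # arithmetic: 50 selected with 5 false -> 0.10
  truth2 <- tibble::tibble(feature_id = paste0("g", 1:50),
    is_de = c(rep(TRUE, 45), rep(FALSE, 5)))
  res2 <- tibble::tibble(feature_id = paste0("g", 1:50),
    p_value = 0.001, lrt_stat = 1, q_value = 0.01)
  expect_equal(observed_fdr(res2, truth2, 0.05)$observed_fdr, 0.10)

  # random ranking recovers the DE base rate among top-k
  set.seed(12)
  K <- 5000
  truth3 <- tibble::tibble(feature_id = paste0("h", 1:K),
    is_de = seq_len(K) <= 500)
  res3 <- tibble::tibble(feature_id = paste0("h", 1:K),
    p_value = runif(K), lrt_stat = 0, q_value = NA_real_)
  tc3 <- tpr_curve(res3, truth3, max_k = 1000)
  expect_lt(abs(tc3$tpr[1000] - 0.10), 3 * sqrt(0.1 * 0.9 / 1000))
})
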