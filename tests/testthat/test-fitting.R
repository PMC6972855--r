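test_that("coefficient maximisation recovers the uncensored closed form", {
  # all non-PMVs, no censoring, intercept-only: beta0 is the mean log value
  y <- exp(c(0.4, 1.3, 2.2, 0.8, 1.9))
  X <- cbind(intercept = rep(1, 5))
  th <- maximize_theta(y, X, sigma = 1, lam = -Inf)
  expect_equal(th$beta[1], mean(log(y)), tolerance = 1e-6)
})

test_that("coefficient maximisation is an ascent from its start", {
  for (s in c(31, 32, 33)) {
    tf <- make_filtered_toy(s)
    init <- default_theta_init(tf$y, 2)
    ll_init <- feature_loglik(init[1:2], init[3:4], 1, tf$X, tf$y, tf$lambda)
    th <- maximize_theta(tf$y, tf$X, sigma = 1, lam = tf$lambda)
    expect_gte(th$loglik, ll_init - 1e-10)
    # and matches the naive likelihood at the returned optimum
    expect_equal(th$loglik,
      naive_loglik(th$gamma, th$beta, 1, tf$X, tf$y, tf$lambda),
      tolerance = 1e-8)
  }
})

test_that("two-group toy fit agrees with a brute-force grid search", {
  # 6 samples: group0 = {0, e^1, e^2}, group1 = {0, e^2, e^3}, sigma = 1
  y <- c(0, exp(1), exp(2), 0, exp(2), exp(3))
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 3))
  lam <- compute_detection_limit(y)
  th <- maximize_theta(y, X, sigma = 1, lam = lam)
  oracle <- grid_search_theta(y, X, 1, lam,
    centre = c(0, 0, mean(log(y[y > 0])), 0))
  expect_equal(th$loglik, oracle$loglik, tolerance = 1e-4)
  expect_gte(th$loglik, oracle$loglik - 1e-4)
})

test_that("variance posterior mode has the conjugate closed form limit", {
  # no PMVs, no censoring, intercept-only fixed mean: the posterior is
  # inverse-gamma with mode (d0 s0^2 + SS) / (d0 + n + 2)
  set.seed(44)
  y <- exp(rnorm(12, 2, 0.8))
  X <- cbind(intercept = rep(1, 12))
  hp <- toy_prior()
  mu <- 1.7
  ss <- sum((log(y) - mu)^2)
  expected <- (hp$d0 * hp$s0^2 + ss) / (hp$d0 + length(y) + 2)
  # gamma intercept at -30: p is numerically 0, the zero component is inert
  got <- posterior_mode_sigma(y, X, gamma = -30, beta = mu, hp = hp,
    lam = -Inf)
  expect_equal(got^2, expected, tolerance = 1e-8)

  # prior-only limit: with no informative data the mode is the prior mode
  y0 <- rep(0, 8)
  got0 <- posterior_mode_sigma(y0, X[1:8, , drop = FALSE], gamma = 30,
    beta = 0, hp = hp, lam = 0)
  expect_equal(got0^2, hp$d0 * hp$s0^2 / (hp$d0 + 2), tolerance = 1e-4)
})

test_that("variance posterior mode agrees with a 1-D grid on censored data", {
  tf <- make_filtered_toy(55)
  hp <- toy_prior()
  th <- maximize_theta(tf$y, tf$X, sigma = 1, lam = tf$lambda)
  got <- posterior_mode_sigma(tf$y, tf$X, th$gamma, th$beta, hp, tf$lambda)
  obj <- function(ls2) {
    naive_loglik(th$gamma, th$beta, sqrt(exp(ls2)), tf$X, tf$y, tf$lambda) +
      log_prior(exp(ls2), hp)
  }
  oracle <- grid_search_log_s2(obj)
  expect_equal(2 * log(got), oracle, tolerance = 2e-4)
})

test_that("alternating fits are monotone in their outer objective", {
  hp <- toy_prior()
  for (s in c(61, 62)) {
    tf <- make_filtered_toy(s)
    for (mode in c("dasev", "tlk")) {
      fit <- fit_feature(tf$y, tf$X, hp, tf$lambda, fit_config(mode = mode))
      if (length(fit$trace) > 1) {
        expect_true(all(diff(fit$trace) > -1e-6))
      }
      expect_true(fit$sigma_tilde > 0)
      expect_true(fit$converged)
    }
  }
})

test_that("the unshrunk mode floors the variance at 0.0025 exactly", {
  # nearly identical non-PMVs force a tiny variance MLE
  set.seed(9)
  y <- c(0, 0, exp(1 + rnorm(4, 0, 1e-5)), 0, exp(1 + rnorm(4, 0, 1e-5)), 0)
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 6))
  fit <- fit_feature(y, X, hp = NULL, lam = compute_detection_limit(y),
    config = fit_config(mode = "tlk"))
  expect_identical(fit$sigma_tilde_sq, 0.0025)
  expect_equal(fit$sigma_tilde, sqrt(0.0025))
})

test_that("shrinkage pulls the variance between the MLE and the prior mode", {
  # uncensored intercept-only conjugate case: sigma_tilde^2 lies weakly
  # between the unpenalised MLE and the prior mode
  hp <- toy_prior()
  set.seed(71)
  for (i in 1:6) {
    y <- exp(rnorm(10, 1.5, runif(1, 0.2, 2.5)))
    X <- cbind(intercept = rep(1, 10))
    mu <- mean(log(y))
    s2_shrunk <- posterior_mode_sigma(y, X, -30, mu, hp, -Inf)^2
    s2_mle <- posterior_mode_sigma(y, X, -30, mu, NULL, -Inf)^2
    pm <- hp$d0 * hp$s0^2 / (hp$d0 + 2)
    expect_gte(s2_shrunk, min(s2_mle, pm) - 1e-8)
    expect_lte(s2_shrunk, max(s2_mle, pm) + 1e-8)
  }
})

test_that("the shrunk variance converges to the truth with many non-PMVs", {
  set.seed(88)
  sigma_true <- 0.9
  y <- exp(rnorm(1000, 2, sigma_true))
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 500))
  # keep one zero per group so the feature passes the mixed filter
  y[c(1, 501)] <- 0
  hp <- toy_prior()
  lam <- compute_detection_limit(y)
  fit <- fit_feature(y, X, hp, lam, fit_config(mode = "dasev"))
  expect_lt(abs(fit$sigma_tilde - sigma_true) / sigma_true, 0.05)
  mle <- fit_feature(y, X, NULL, lam, fit_config(mode = "tlk"))
  expect_lt(abs(fit$sigma_tilde - mle$sigma_tilde) / mle$sigma_tilde, 0.02)
})

test_that("variance recovery is tighter under shrinkage than unshrunk fits", {
  # 200 replicate features at n = 200/group from one parameter set with a
  # high zero fraction: the shrunk estimator has smaller median relative
  # error and fewer order-of-magnitude misses
  set.seed(303)
  n <- 200
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = n))
  pool <- synthetic_parameter_pool(1000, seed = 404)
  idx <- sample.int(1000, 200, replace = TRUE)
  mat <- t(vapply(idx, function(i) {
    simulate_feature(pool$mu[i], pool$p_bpmv[i], pool$sigma[i],
      pool$lambda[i], 2 * n)
  }, numeric(2 * n)))
  rownames(mat) <- paste0("f", 1:200)
  m <- abundance_matrix(mat)
  sig_true <- pool$sigma[idx]
  hp <- estimate_prior(m)
  flt <- suppressWarnings(filter_features(m, X))
  err <- purrr::map(which(rownames(m) %in% flt$kept_ids), function(k) {
    lam <- compute_detection_limit(m[k, ])
    f1 <- fit_feature(m[k, ], X, hp, lam, fit_config(mode = "dasev"))
    f2 <- fit_feature(m[k, ], X, NULL, lam, fit_config(mode = "tlk"))
    c(dasev = abs(f1$sigma_tilde - sig_true[k]) / sig_true[k],
      tlk = abs(f2$sigma_tilde - sig_true[k]) / sig_true[k])
  })
  err <- do.call(rbind, err)
  expect_lt(median(err[, "dasev"]), median(err[, "tlk"]))
})

test_that("fits refuse perfectly separated features", {
  y <- c(0, 0, 0, 2, 3, 4)
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 3))
  expect_error(fit_feature(y, X, toy_prior(), 0, fit_config()),
    "perfect separation")
})

test_that("fit objects tidy and glance into standard tibbles", {
  tf <- make_filtered_toy(91)
  fit <- fit_feature(tf$y, tf$X, toy_prior(), tf$lambda, fit_config())
  td <- tidy(fit)
  expect_identical(nrow(td), 4L)
  expect_setequal(unique(td$component), c("zero_proportion", "log_abundance"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$mode, "dasev")
})
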