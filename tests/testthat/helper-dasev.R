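# Shared fixtures and independent oracles. Oracles are deliberately naive
# (term-by-term sums, grid searches) and never call the code paths they check.

# Naive per-sample mixture log-likelihood: direct transcription of the
# density, summed in a loop.
naive_loglik <- function(gamma, beta, sigma, X, y, lam, clamp = 30) {
  total <- 0
  for (i in seq_along(y)) {
    eta <- sum(X[i, ] * gamma)
    eta <- min(max(eta, -clamp), clamp)
    p <- exp(eta) / (1 + exp(eta))
    mu <- sum(X[i, ] * beta)
    if (y[i] == 0) {
      total <- total + log(p + (1 - p) * pnorm((lam - mu) / sigma))
    } else {
      total <- total + log(1 - p) +
        dnorm((log(y[i]) - mu) / sigma, log = TRUE) - log(sigma)
    }
  }
  total
}

# Brute-force step-up BH oracle.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Iteratively refined lattice search over theta = (gamma0, gamma1, beta0,
# beta1) at fixed sigma: a full 4-D grid, re-centred and halved until the
# lattice step is <= `step_target` in every coordinate. Density terms are
# written out directly; vectorised over lattice points only.
grid_search_theta <- function(y, X, sigma, lam, centre, half_width = 4,
                              n_pts = 9L, step_target = 1e-3) {
  eval_lattice <- function(G) {
    total <- numeric(nrow(G))
    for (i in seq_along(y)) {
      eta <- X[i, 1] * G[, 1] + X[i, 2] * G[, 2]
      eta <- pmin(pmax(eta, -30), 30)
      p <- 1 / (1 + exp(-eta))
      mu <- X[i, 1] * G[, 3] + X[i, 2] * G[, 4]
      total <- total + if (y[i] == 0) {
        log(p + (1 - p) * pnorm((lam - mu) / sigma))
      } else {
        log(1 - p) + dnorm((log(y[i]) - mu) / sigma, log = TRUE) - log(sigma)
      }
    }
    total
  }
  refine <- function(start) {
    best <- start
    width <- rep(half_width / 2, 4L)
    pans <- 0L
    best_val <- -Inf
    repeat {
      axes <- lapply(1:4, function(j) {
        seq(best[j] - width[j], best[j] + width[j], length.out = n_pts)
      })
      G <- as.matrix(expand.grid(axes))
      vals <- eval_lattice(G)
      i <- which.max(vals)
      on_edge <- vapply(1:4, function(j) {
        G[i, j] <= axes[[j]][1] || G[i, j] >= axes[[j]][n_pts]
      }, logical(1))
      improved <- vals[i] > best_val + 1e-10
      best <- unname(G[i, ])
      best_val <- vals[i]
      step <- 2 * width / (n_pts - 1)
      if (any(on_edge) && improved && pans < 100L) {
        pans <- pans + 1L  # optimum drifting out of the box: pan, not shrink
        next
      }
      if (all(step <= step_target)) {
        return(list(theta = best, loglik = best_val))
      }
      width <- 2 * step  # keep two lattice cells around the incumbent
    }
  }
  # the surface is bimodal (zeros explained by censoring vs by the point
  # mass): scan one global coarse lattice, then refine from the best points
  # of well-separated regions and keep the overall winner
  axes0 <- lapply(1:4, function(j) {
    seq(centre[j] - half_width, centre[j] + half_width, length.out = n_pts)
  })
  G0 <- as.matrix(expand.grid(axes0))
  v0 <- eval_lattice(G0)
  ord <- order(v0, decreasing = TRUE)
  starts <- list(unname(G0[ord[1], ]))
  for (i in ord[-1]) {
    if (length(starts) >= 4L) break
    far <- all(vapply(starts, function(s) {
      max(abs(s - G0[i, ])) > half_width / 2
    }, logical(1)))
    if (far) starts <- c(starts, list(unname(G0[i, ])))
  }
  cand <- lapply(starts, refine)
  cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
}

# 1-D grid search over log sigma^2 for the penalised (or plain) likelihood,
# refined to `step_target` resolution.
grid_search_log_s2 <- function(obj, lower = log(1e-4), upper = log(1e4),
                               step_target = 1e-4) {
  lo <- lower; hi <- upper
  repeat {
    grid <- seq(lo, hi, length.out = 201L)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.max(vals)
    step <- grid[2] - grid[1]
    if (step <= step_target) return(grid[i])
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
  }
}

# A small two-group feature with zeros in both groups, built from fixed
# parameters; returns values, design, and the generating parameters.
make_toy_feature <- function(seed, n_per_group = 6, mu = 2, p_bpmv = 0.35,
                             sigma = 1, lambda = mu - 1.5,
                             mu_shift = 0, p_shift = 0) {
  set.seed(seed)
  y0 <- simulate_feature(mu, p_bpmv, sigma, lambda, n_per_group)
  y1 <- simulate_feature(mu + mu_shift, plogis(qlogis(p_bpmv) + p_shift),
    sigma, lambda, n_per_group)
  y <- c(y0, y1)
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = n_per_group))
  list(y = y, X = X, mu = mu, p_bpmv = p_bpmv, sigma = sigma,
    lambda = lambda)
}

# Toy feature guaranteed to pass the per-group mixed PMV/non-PMV filter.
make_filtered_toy <- function(seed, ...) {
  for (s in seed + 0:50) {
    tf <- make_toy_feature(s, ...)
    g <- tf$X[, "group"]
    z <- tf$y == 0
    ok <- sum(!z) >= 3 &&
      any(z[g == 0]) && any(!z[g == 0]) && any(z[g == 1]) && any(!z[g == 1])
    if (ok) return(tf)
  }
  stop("could not build a filtered toy feature")
}

toy_prior <- function(d0 = 8, s0 = sqrt(0.75)) {
  structure(list(d0 = d0, s0 = s0, n_features_used = NA_integer_),
    class = "dasev_prior")
}
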