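test_that("generator kernel limits match closed forms", {
  cents <- default_centroids(3, radius = 1)
  # pure frequency with uniform f -> uniform matrix
  cfg_u <- generator_config(k = 3, centroids = cents,
                            target_freqs = rep(1 / 3, 3),
                            w_dist = 0, w_freq = 1, n_blocks = 10)
  expect_equal(unname(build_generator_matrix(cfg_u)$probs),
               matrix(1 / 3, 3, 3))

  # pure frequency, f = (.5, .3, .2): every row equals f after
  # normalization (f_i cancels row-wise)
  cfg_f <- generator_config(k = 3, centroids = cents,
                            target_freqs = c(0.5, 0.3, 0.2),
                            w_dist = 0, w_freq = 1, n_blocks = 10)
  P <- build_generator_matrix(cfg_f)$probs
  for (i in 1:3) expect_equal(unname(P[i, ]), c(0.5, 0.3, 0.2))

  # pure distance with a tiny length scale -> identity-dominated
  cfg_d <- generator_config(k = 3, centroids = cents,
                            target_freqs = rep(1 / 3, 3),
                            w_dist = 1, w_freq = 0, length_scale = 0.05,
                            n_blocks = 10)
  expect_gt(min(diag(build_generator_matrix(cfg_d)$probs)), 0.999)
})

test_that("generator rows are stochastic to 1e-12 across random configs", {
  set.seed(3)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    f <- as.numeric(stats::rgamma(k, 1)); f <- f / sum(f)
    cfg <- generator_config(
      k = k, centroids = matrix(rnorm(3 * k), k, 3), target_freqs = f,
      w_dist = runif(1), w_freq = runif(1, 0.01, 1),
      length_scale = runif(1, 0.2, 3), n_blocks = 10
    )
    P <- build_generator_matrix(cfg)$probs
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  }
})

test_that("chain sampling honours degenerate and periodic kernels", {
  id <- diag(4)
  expect_equal(simulate_states(id, 20, seed = 1, init_state = 3),
               rep(3L, 20))
  flip <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  s <- simulate_states(flip, 11, seed = 2, init_state = 1)
  expect_equal(s, rep(c(1L, 2L), length.out = 11))
})

test_that("long-run state frequencies match the stationary distribution", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0.3, w_freq = 0.7, length_scale = 1,
                          n_blocks = 10)
  P <- build_generator_matrix(cfg)$probs
  pi_hat <- stationary_oracle(P)
  expect_equal(stationary_distribution(P), unname(pi_hat), tolerance = 1e-8)

  n <- 1e5
  s <- simulate_states(P, n, seed = 9, init_probs = pi_hat)
  freq <- state_frequencies(s, 4)
  # 3 standard errors, conservatively ignoring autocorrelation shrinkage
  se <- sqrt(pi_hat * (1 - pi_hat) / n)
  expect_true(all(abs(freq - pi_hat) < 3 * pmax(se, 0.004)))
})

test_that("noiseless emission sits exactly on back-transformed centroids", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = rep(0.25, 4), emission_sd = 0,
                          n_blocks = 10)
  states <- c(1L, 3L, 4L, 2L, 2L)
  ser <- emit_blocks(states, states, cfg, cfg, seed = 5)
  expected <- sweep(sweep(cfg$centroids[states, ], 2, cfg$feature_sds, "*"),
                    2, cfg$feature_means, "+")
  expect_equal(unname(as.matrix(ser[, c("pat_pos", "pat_neg", "pat_abs")])),
               unname(expected))
  expect_equal(attr(ser, "clip_rate"), 0)
})

test_that("clustering noiseless and mildly noisy emissions recovers the labels", {
  # centroids must vary on every feature or standardization degenerates
  cents <- matrix(c(1, 1, -1, -1, 1, 1, 1, -1, 1), 3, byrow = TRUE)
  cfg0 <- generator_config(k = 3, centroids = cents,
                           target_freqs = c(0.5, 0.3, 0.2), emission_sd = 0,
                           n_blocks = 10)
  set.seed(21)
  states <- sample.int(3, 300, replace = TRUE, prob = cfg0$target_freqs)
  agreement <- function(cfg, states) {
    ser <- emit_blocks(states, states, cfg, cfg, seed = 3)
    std <- standardize_features(role_features(ser, "patient"))
    model <- fit_states(std$z, k = 3, n_restarts = 10, seed = 4,
                        constants = std)
    tab <- table(model$labels, states)
    sum(apply(tab, 1, max)) / length(states)
  }
  expect_equal(agreement(cfg0, states), 1) # separated blobs: perfect
  cfg2 <- generator_config(k = 3, centroids = cents,
                           target_freqs = c(0.5, 0.3, 0.2), emission_sd = 0.2,
                           n_blocks = 10)
  expect_gte(agreement(cfg2, states), 0.95)
})

test_that("dyad coupling spans independence to full driving", {
  base <- function(kappa, seed) {
    cfg <- generator_config(k = 4, centroids = default_centroids(4),
                            target_freqs = c(0.4, 0.3, 0.2, 0.1),
                            w_dist = 0, w_freq = 1, n_blocks = 800,
                            coupling = kappa, seed = seed)
    simulate_dyad(cfg, cfg, seed = seed)
  }
  # kappa = 1, identity map: therapist mirrors patient exactly
  full <- base(1, 11)
  expect_equal(full$ther_states$labels, full$pat_states$labels)

  # kappa = 0: joint table shows no association (alpha = 0.01)
  ind <- base(0, 12)
  tab <- table(ind$pat_states$labels, ind$ther_states$labels)
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)

  # correlation of the P2T matrix with the mirror (identity) pattern
  # increases with coupling at a fixed seed set
  p2t_cor <- vapply(c(0, 0.5, 1), function(kap) {
    rs <- vapply(1:5, function(s) {
      sim <- base(kap, 100 + s)
      A <- dyad_mtm(sim$pat_states, sim$ther_states, 4, "P2T")
      defined <- rowSums(A$counts) > 0
      stats::cor(as.vector(A$probs[defined, ]),
                 as.vector(diag(4)[defined, ]))
    }, 0)
    mean(rs)
  }, 0)
  expect_true(all(diff(p2t_cor) > 0))
})

test_that("mismatched dyad lengths and invalid noise are rejected", {
  cfg <- generator_config(k = 3, centroids = default_centroids(3),
                          target_freqs = c(0.5, 0.3, 0.2), n_blocks = 10)
  cfg2 <- generator_config(k = 3, centroids = default_centroids(3),
                           target_freqs = c(0.5, 0.3, 0.2), n_blocks = 20)
  expect_error(simulate_dyad(cfg, cfg2), "n_blocks")
  expect_error(emit_blocks(1:3, 1:4, cfg), "equal length")
  expect_error(generator_config(k = 3, centroids = default_centroids(3),
                                target_freqs = c(0.5, 0.3, 0.2),
                                emission_sd = -1, n_blocks = 10),
               "emission_sd")
})

test_that("generator configs round-trip through their file form", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0.25, length_scale = 1.7, n_blocks = 123,
                          coupling = 0.4, seed = 99)
  f <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("target and realized stationary frequencies are reported distinctly", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0.5, w_freq = 0.5, n_blocks = 10)
  P <- build_generator_matrix(cfg)
  pi_real <- stationary_distribution(P)
  # with a distance component they differ; no silent equating
  expect_gt(max(abs(pi_real - cfg$target_freqs)), 0.01)
})
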