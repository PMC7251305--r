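test_that("centroid distances are Euclidean, symmetric, zero-diagonal", {
  m <- matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE)
  d <- centroid_distances(m)
  expect_equal(unname(d), matrix(c(0, 5, 5, 0), 2))

  set.seed(30)
  cm <- matrix(rnorm(15), 5, 3)
  d5 <- centroid_distances(cm)
  # brute-force oracle
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d5[i, j], sqrt(sum((cm[i, ] - cm[j, ])^2)))
  }
  expect_equal(diag(d5), rep(0, 5), ignore_attr = TRUE)
})

test_that("design table covers active-state cells and round-trips y", {
  set.seed(31)
  s <- sample.int(6, 400, replace = TRUE)
  T6 <- mtm(s, 8)
  freqs <- state_frequencies(s, 8)
  dists <- centroid_distances(matrix(rnorm(24), 8, 3))
  des <- build_design(T6, dists, freqs)
  expect_equal(nrow(des), 36)
  expect_equal(des$y, T6$probs[cbind(des$i, des$j)])
  expect_equal(des$x_comp, freqs[des$i] * freqs[des$j])
  expect_equal(des$x_freqj, freqs[des$j])
  expect_true(all(des$x_dist[des$i == des$j] == 0))
  expect_true(all(des$x_dist[des$i != des$j] > 0))

  # frequencies (0.5, 0.3, 0.2): composite for (1, 3) is 0.10
  s3 <- rep(c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L), 20)
  T3 <- mtm(s3, 3)
  f3 <- state_frequencies(s3, 3)
  expect_equal(f3, c(0.5, 0.3, 0.2))
  d3 <- centroid_distances(matrix(rnorm(9), 3, 3))
  des3 <- build_design(T3, d3, f3)
  expect_equal(des3$x_comp[des3$i == 1 & des3$j == 3], 0.10)

  no_diag <- build_design(T6, dists, freqs, include_diagonal = FALSE)
  expect_equal(nrow(no_diag), 30)
  expect_error(build_design(mtm(c(1L, 2L, 1L), 2), dists[1:2, 1:2],
                            c(0.5, 0.5)), "fewer than 5")
})

test_that("standardized OLS matches a normal-equations oracle", {
  set.seed(32)
  for (rep in 1:10) {
    n <- 25
    des <- tibble::tibble(
      i = rep(1:5, each = 5), j = rep(1:5, 5),
      x_dist = as.numeric(centroid_distances(matrix(rnorm(15), 5, 3))),
      x_freqj = runif(n), x_comp = runif(n)
    )
    des$y <- 0.4 - 0.3 * des$x_dist + 2 * des$x_comp + rnorm(n, 0, 0.2)
    fit <- fit_model(des, "full")
    # oracle: solve the normal equations on z-scored columns
    zs <- function(v) (v - mean(v)) / sd(v)
    X <- cbind(zs(des$x_dist), zs(des$x_comp))
    yz <- zs(des$y)
    beta <- solve(t(X) %*% X, t(X) %*% yz)
    expect_equal(fit$beta_dist, beta[1], tolerance = 1e-10)
    expect_equal(fit$beta_comp, beta[2], tolerance = 1e-10)
    pred <- X %*% beta
    r2 <- 1 - sum((yz - pred)^2) / sum(yz^2)
    expect_equal(fit$r2, r2, tolerance = 1e-10)
    # single-regressor beta equals the plain correlation
    fit1 <- fit_model(des, "distance")
    expect_equal(fit1$beta_dist, cor(des$y, des$x_dist), tolerance = 1e-10)
  }
})

test_that("exact relations hold: r2 = r^2, adjusted R2 formula, F-test p", {
  set.seed(33)
  des <- tibble::tibble(
    i = rep(1:3, each = 3), j = rep(1:3, 3),
    x_dist = runif(9, 0, 2), x_freqj = runif(9), x_comp = runif(9)
  )
  des$x_dist[des$i == des$j] <- 0
  des$y <- 0.2 * des$x_comp + rnorm(9, 0, 0.1)
  for (mode in c("distance", "freq_j", "composite", "full")) {
    fit <- fit_model(des, mode)
    expect_equal(fit$r^2, fit$r2, tolerance = 1e-12)
    expect_equal(fit$adj_r2,
                 1 - (1 - fit$r2) * (fit$n_cells - 1) /
                   (fit$n_cells - fit$k_predictors - 1),
                 tolerance = 1e-12)
    expect_lte(fit$adj_r2, fit$r2)
  }
  # y affine in x_comp -> exact composite fit
  des2 <- des
  des2$y <- 3 + 2 * des2$x_comp
  exact <- suppressWarnings(fit_model(des2, "full")) # perfect fit
  expect_equal(exact$beta_comp, 1, tolerance = 1e-8)
  expect_equal(exact$beta_dist, 0, tolerance = 1e-8)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
})

test_that("model F p-value agrees with a permutation oracle", {
  set.seed(34)
  des <- tibble::tibble(
    i = rep(1:4, each = 4), j = rep(1:4, 4),
    x_dist = runif(16, 0, 2), x_freqj = runif(16), x_comp = runif(16)
  )
  des$y <- 0.5 * des$x_comp + rnorm(16, 0, 0.35)
  fit <- fit_model(des, "composite")
  obs_r2 <- fit$r2
  perm <- vapply(1:4000, function(i) {
    d2 <- des; d2$y <- sample(d2$y)
    summary(stats::lm(scale(y) ~ scale(x_comp), data = d2))$r.squared
  }, 0)
  p_perm <- mean(perm >= obs_r2)
  expect_lt(abs(p_perm - fit$p_model), 3 * sqrt(0.05 / 4000) + 0.015)
})

test_that("degenerate designs are rejected", {
  des <- tibble::tibble(i = rep(1:3, each = 3), j = rep(1:3, 3),
                        x_dist = runif(9), x_freqj = runif(9),
                        x_comp = runif(9), y = 0.5)
  expect_error(fit_model(des, "full"), "zero variance in y")
  des$y <- runif(9)
  des$x_comp <- 2 * des$x_dist + 1
  expect_error(fit_model(des, "full"), "collinear")
})

test_that("published coefficients reproduce the printed beta ratio", {
  pub <- published_fits()
  george <- pub$patient[pub$patient$subject_id == "George", ]
  expect_equal(abs(george$beta_comp) / abs(george$beta_dist), 2.403,
               tolerance = 5e-4)
  # every printed per-subject ratio is consistent with its betas
  both <- pub$both
  expect_equal(abs(both$beta_comp) / abs(both$beta_dist), both$beta_ratio,
               tolerance = 2e-2)
})

test_that("cohort summary takes signed means and the cross-role distance ratio", {
  pub <- published_fits()
  cs <- cohort_summary(pub$both)
  pat <- cs$by_role[cs$by_role$role == "patient", ]
  ther <- cs$by_role[cs$by_role$role == "therapist", ]
  expect_equal(pat$beta_dist, mean(pub$patient$beta_dist))
  expect_equal(pat$beta_ratio, mean(pub$patient$beta_ratio))
  expect_equal(cs$cross_role_dist_ratio,
               abs(mean(pub$patient$beta_dist)) /
                 abs(mean(pub$therapist$beta_dist)))
  # single-subject role equals that subject
  single <- cohort_summary(pub$patient[1, ])
  expect_equal(single$by_role$beta_dist, pub$patient$beta_dist[1])
})

test_that("mode comparison ranks by adjusted R2 and recovers the generating law", {
  r_freq <- transition_recovery(0, 1, n_blocks = 5000, seed = 5)
  ranks <- r_freq$modes
  expect_equal(ranks$rank, order(order(-ranks$adj_r2)))
  expect_lt(ranks$adj_r2[ranks$mode == "distance"],
            ranks$adj_r2[ranks$mode == "composite"])
  expect_lt(ranks$adj_r2[ranks$mode == "distance"],
            ranks$adj_r2[ranks$mode == "full"])

  r_dist <- transition_recovery(1, 0, n_blocks = 5000, seed = 5,
                                length_scale = 0.7)
  expect_lt(r_dist$fit$beta_dist, -0.5)
  d_modes <- r_dist$modes
  expect_gt(d_modes$adj_r2[d_modes$mode == "distance"],
            d_modes$adj_r2[d_modes$mode == "freq_j"])
})

test_that("pure-noise responses yield near-zero fits at large n", {
  set.seed(36)
  k <- 8
  dists <- centroid_distances(matrix(rnorm(24), 8, 3))
  f <- as.numeric(rgamma(8, 2)); f <- f / sum(f)
  grid <- expand.grid(i = 1:8, j = 1:8)
  des <- tibble::tibble(
    i = grid$i, j = grid$j, y = runif(64),
    x_dist = dists[cbind(grid$i, grid$j)],
    x_freqj = f[grid$j], x_comp = f[grid$i] * f[grid$j]
  )
  for (mode in c("distance", "freq_j", "composite", "full")) {
    expect_lt(fit_model(des, mode)$r2, 0.15)
  }
})

test_that("full-model signs recover across the generator weight grid", {
  grid <- list(c(0, 1), c(0.5, 0.5), c(1, 0), c(0.5, 1), c(1, 0.5), c(1, 1))
  n_runs <- 8
  for (w in grid) {
    fits <- lapply(seq_len(n_runs), function(s) {
      transition_recovery(w[1], w[2], n_blocks = 5000, seed = 400 + s,
                          length_scale = 0.7)$fit
    })
    bc <- vapply(fits, `[[`, 0, "beta_comp")
    bd <- vapply(fits, `[[`, 0, "beta_dist")
    expect_true(all(bc > 0))
    if (w[1] > 0) expect_true(all(bd <= 0))
  }
})
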