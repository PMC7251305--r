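test_that("transition counting matches hand-enumerated examples", {
  c1 <- count_transitions(c(1L, 1L, 1L, 1L), k = 2)
  expect_equal(c1[1, 1], 3L)
  expect_equal(sum(c1), 3L)

  c2 <- count_transitions(c(1L, 2L, 1L, 2L), k = 2)
  expect_equal(c2[1, 2], 2L)
  expect_equal(c2[2, 1], 1L)

  expect_error(count_transitions(c(1L, 5L), k = 4), "outside 1..k")
  expect_error(count_transitions(3L, k = 4), "at least 2")

  # property: total transitions = length - 1
  set.seed(13)
  for (rep in 1:10) {
    s <- sample.int(5, sample(10:60, 1), replace = TRUE)
    expect_equal(sum(count_transitions(s, 5)), length(s) - 1L)
  }
})

test_that("transition matrices are row-stochastic with undefined rows kept NA", {
  s <- c(3L, 3L, 3L, 3L)
  T1 <- mtm(s, k = 5)
  expect_equal(T1$probs[3, 3], 1)
  expect_true(all(is.na(T1$probs[c(1, 2, 4, 5), ])))

  set.seed(14)
  for (rep in 1:10) {
    s <- sample.int(6, 80, replace = TRUE)
    Tm <- mtm(s, 8)
    defined <- rowSums(Tm$counts) > 0
    expect_true(all(abs(rowSums(Tm$probs[defined, , drop = FALSE]) - 1) < 1e-9))
    expect_true(all(is.na(Tm$probs[!defined, ])))
    expect_equal(Tm$probs[defined, ],
                 Tm$counts[defined, ] / rowSums(Tm$counts)[defined])
  }
})

test_that("estimated matrix converges to the generating kernel", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0.3, w_freq = 0.7, n_blocks = 10)
  P <- build_generator_matrix(cfg)$probs
  s <- simulate_states(P, 1e5, seed = 4,
                       init_probs = stationary_oracle(P))
  est <- mtm(s, 4)
  expect_lt(max(abs(est$probs - P)), 0.02)
})

test_that("mtm is equivariant under state relabeling", {
  set.seed(15)
  s <- sample.int(4, 200, replace = TRUE)
  perm <- c(3L, 1L, 4L, 2L)
  T_orig <- mtm(s, 4)
  T_perm <- mtm(perm[s], 4)
  expect_equal(unname(T_perm$probs[perm, perm]), unname(T_orig$probs))
})

test_that("state frequencies sum to one and track the printed occurrence profile", {
  expect_equal(state_frequencies(rep(2L, 9), 3), c(0, 1, 0))
  # printed occurrence counts for the six surviving states of the
  # worked example: frequencies proportional to counts
  counts <- c(2191, 1494, 1484, 1115, 709, 371)
  labels <- rep(1:6, times = counts)
  freq <- state_frequencies(labels, 8)
  expect_equal(sum(freq), 1)
  expect_equal(freq[1:6], counts / sum(counts))
  expect_equal(freq[7:8], c(0, 0))
})

test_that("dyad pairing aligns on shared blocks in both directions", {
  pat <- state_sequence(c(1L, 2L, 3L, 1L), t = c(0L, 1L, 2L, 3L),
                        role = "patient")
  ther <- state_sequence(c(2L, 2L, 1L), t = c(0L, 2L, 3L),
                         role = "therapist")
  p2t <- dyad_sequence(pat, ther, "P2T")
  expect_equal(p2t[, "from"], c(1L, 3L, 1L))
  expect_equal(p2t[, "to"], c(2L, 2L, 1L))
  t2p <- dyad_sequence(pat, ther, "T2P")
  expect_equal(t2p[, "from"], c(2L, 2L))
  expect_equal(t2p[, "to"], c(3L, 1L))

  none <- state_sequence(1L, t = 9L, role = "therapist")
  expect_error(dyad_sequence(pat, none), "no aligned")
})

test_that("fully coupled dyads give an identity-supported P2T matrix", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0, w_freq = 1, n_blocks = 400,
                          coupling = 1, seed = 31)
  sim <- simulate_dyad(cfg, cfg, seed = 31)
  A <- dyad_mtm(sim$pat_states, sim$ther_states, 4, "P2T")
  visited <- which(rowSums(A$counts) > 0)
  expect_equal(unname(A$probs[visited, visited]),
               diag(length(visited)))
})

test_that("independent chains give P2T rows near the therapist marginal", {
  cfg <- generator_config(k = 4, centroids = default_centroids(4),
                          target_freqs = c(0.4, 0.3, 0.2, 0.1),
                          w_dist = 0, w_freq = 1, n_blocks = 8000,
                          coupling = 0, seed = 77)
  sim <- simulate_dyad(cfg, cfg, seed = 77)
  A <- dyad_mtm(sim$pat_states, sim$ther_states, 4, "P2T")
  marg <- state_frequencies(sim$ther_states, 4)
  defined <- which(rowSums(A$counts) > 0)
  for (i in defined) {
    expect_lt(max(abs(A$probs[i, ] - marg)), 0.05)
  }
})

test_that("published dyad rows are valid probability rows", {
  p2t <- george_p2t_probs()
  expect_equal(sum(p2t[1, ], na.rm = TRUE), 1, tolerance = 1e-9)
  defined <- which(!is.na(p2t[, 1]))
  for (i in defined) {
    expect_equal(sum(p2t[i, ], na.rm = TRUE), 1, tolerance = 2e-3)
  }
})

test_that("row-max flags mark all tied maxima of the published matrix", {
  G <- mtm_from_probs(george_probs())
  flags <- row_max_flags(G)
  expect_true(flags[1, 8])
  expect_true(flags[2, 3] && flags[2, 7]) # tie at 0.325: both flagged
  expect_true(flags[3, 8])
  expect_true(flags[4, 8])
  expect_true(flags[7, 7])
  expect_true(flags[8, 8])
  expect_equal(sum(flags), 7)
  expect_true(all(!flags[c(5, 6), ]))
})

test_that("network export writes one edge per nonzero cell in both formats", {
  G <- mtm_from_probs(george_probs())
  f_dot <- withr::local_tempfile(fileext = ".dot")
  edges <- export_network(G, f_dot, "dot")
  expect_equal(nrow(edges), sum(G$probs > 0, na.rm = TRUE))
  expect_true(file.exists(f_dot))
  expect_gt(length(readLines(f_dot)), 10)

  f_gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(G, f_gml, "graphml")
  gml <- readLines(f_gml)
  expect_equal(sum(grepl("<edge ", gml)), nrow(edges))

  idm <- mtm_from_probs(diag(4))
  e_id <- export_network(idm, withr::local_tempfile(fileext = ".dot"), "dot")
  expect_equal(nrow(e_id), 4)
  expect_true(all(e_id$from == e_id$to))
  expect_true(all(edges$is_row_max %in% c(0L, 1L)))
  expect_error(export_network(G, "x.foo", "foo"))
})

test_that("matrix CSV export leaves undefined rows blank", {
  G <- mtm_from_probs(george_probs())
  f <- withr::local_tempfile(fileext = ".csv")
  write_mtm_csv(G, f)
  rows <- utils::read.csv(f, check.names = FALSE,
                          colClasses = "character")
  expect_equal(nrow(rows), 8)
  expect_true(all(rows[5, -1] == ""))
  expect_true(all(rows[6, -1] == ""))
  expect_equal(as.numeric(rows[2, "3"]), 0.325)
})
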