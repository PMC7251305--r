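#' One transition-law parameter-recovery run
#'
#' Generates a state chain under a known transition kernel (weights
#' `w_dist`, `w_freq`), estimates its transition matrix, and fits the
#' transition-law regressions using the true centroid geometry and the
#' realized state frequencies. Used to check that the regression
#' recovers the signs and the ranking of the generating law: a
#' frequency-driven generator should yield `beta_comp > 0` with
#' `beta_dist` near zero and the composite/full modes outranking the
#' distance-only mode, while a distance-driven generator with a short
#' length scale should yield a clearly negative `beta_dist`.
#'
#' @param w_dist,w_freq generator kernel weights.
#' @param n_blocks chain length (default 5000).
#' @param seed RNG seed.
#' @param length_scale distance-kernel scale (default 1).
#' @param k number of states (default 8; no rare states, so every row of
#'   the estimated matrix is defined).
#' @return A list with `fit` (full-mode [fit_model()] row), `modes`
#'   ([compare_modes()] table), `truth` (generator matrix) and
#'   `frequencies` (realized).
#' @export
transition_recovery <- function(w_dist, w_freq, n_blocks = 5000L, seed = 1L,
                                length_scale = 1) {
  k <- 8L
  config <- generator_config(
    k = k, target_freqs = default_target_freqs(k, n_rare = 0L),
    w_dist = w_dist, w_freq = w_freq, length_scale = length_scale,
    n_blocks = n_blocks, seed = seed
  )
  T0 <- build_generator_matrix(config)
  labels <- simulate_states(T0, n_blocks, seed = derive_seed(seed, 1L),
                            init_probs = config$target_freqs)
  est <- mtm(labels, k)
  freqs <- state_frequencies(labels, k)
  dists <- centroid_distances(config$centroids)
  design <- build_design(est, dists, freqs)
  list(
    fit = fit_model(design, "full"),
    modes = compare_modes(est, dists, freqs),
    truth = T0, frequencies = freqs
  )
}

#' Simulate a chain with a mid-series occupancy shift
#'
#' A k-state chain with identical rows (i.i.d. states) whose state-1
#' occupancy switches from `p1_first` to `p1_last` at the midpoint, the
#' remaining mass spread evenly over the other states. The canonical
#' alternative for drift-screen power studies; with
#' `p1_first == p1_last` it is a stationary chain for type-I studies.
#'
#' @param n series length.
#' @param p1_first,p1_last state-1 mass before and after the midpoint.
#' @param k number of states (default 4).
#' @param seed RNG seed.
#' @return Integer label vector of length `n`.
#' @export
simulate_occupancy_shift <- function(n, p1_first = 0.3, p1_last = 0.05,
                                     k = 4L, seed = 1L) {
  stopifnot(n >= 2L, k >= 2L, p1_first < 1, p1_last < 1)
  row_for <- function(p1) c(p1, rep((1 - p1) / (k - 1L), k - 1L))
  half <- n %/% 2L
  set.seed(seed)
  first <- sample.int(k, half, replace = TRUE, prob = row_for(p1_first))
  last <- sample.int(k, n - half, replace = TRUE, prob = row_for(p1_last))
  c(first, last)
}
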