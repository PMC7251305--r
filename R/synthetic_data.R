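#' Default state centroids
#'
#' Places the k states at sign-pattern vertices of the standardized
#' (pos, neg, abs) feature cube, scaled to `radius`. For k = 8 these are
#' the eight corners of the cube — each state is a distinct profile of
#' above-/below-average positive tone, negative tone and abstraction
#' (the all-minus corner playing the role of a "silence" state).
#'
#' @param k number of states (at most 8 for the cube layout).
#' @param radius half-width of the cube in standardized units.
#' @return k x 3 matrix of standardized centroids.
#' @export
default_centroids <- function(k = 8L, radius = 1) {
  cube <- as.matrix(expand.grid(pos = c(1, -1), neg = c(1, -1),
                                abs = c(1, -1)))
  if (k > nrow(cube)) {
    stop("cube layout supports at most 8 states; supply centroids",
         call. = FALSE)
  }
  m <- cube[seq_len(k), , drop = FALSE] * radius
  rownames(m) <- seq_len(k)
  m
}

#' Default target state frequencies
#'
#' Occupancy profiles emulating a brief-psychotherapy state
#' distribution: a handful of dominant states with geometrically
#' decaying shares plus `n_rare` very scarcely populated states (share
#' `rare_share` each, below the 1% pruning threshold). The patient
#' profile carries 2 rare states and the therapist profile 3, so that
#' 1%-occupancy pruning of an 8-state solution leaves 6 and 5 active
#' states respectively.
#'
#' @param k number of states.
#' @param n_rare number of sub-threshold states.
#' @param rare_share occupancy share of each rare state.
#' @return Length-k probability vector (sums to 1), decreasing.
#' @export
default_target_freqs <- function(k = 8L, n_rare = 2L, rare_share = 0.004) {
  n_major <- k - n_rare
  if (n_major < 1L) stop("`n_rare` must be below `k`", call. = FALSE)
  major <- 0.65^seq(0, n_major - 1L)
  major <- major / sum(major) * (1 - n_rare * rare_share)
  c(major, rep(rare_share, n_rare))
}

#' Synthetic dyad generator configuration
#'
#' Parameters of the ground-truth transition law used to simulate one
#' speaker's symbolic dynamic and its word-block emissions. The
#' transition kernel mixes a centroid-distance penalty and a
#' state-frequency attraction:
#' `T_ij proportional to w_freq * f_i * f_j + w_dist * exp(-d_ij / length_scale)`,
#' row-normalized. Pure frequency weights (`w_dist = 0`) give the
#' ergodic, destination-frequency law; pure distance weights give the
#' distance-dependent law; mixtures give the intermediate random-walk
#' regime.
#'
#' @param k number of states.
#' @param centroids k x 3 standardized centroid matrix.
#' @param target_freqs length-k probability vector `f`.
#' @param w_dist,w_freq non-negative kernel weights (not both zero).
#' @param length_scale distance-kernel scale `lambda > 0`.
#' @param emission_sd Gaussian emission noise sd in standardized units.
#' @param n_blocks series length.
#' @param coupling therapist-copies-patient probability `kappa` in
#'   \[0, 1\] (used by [simulate_dyad()]).
#' @param seed integer RNG seed.
#' @param feature_means,feature_sds per-feature constants mapping
#'   standardized emissions back to the \[0, 1\] frequency scale.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(k = 8L,
                             centroids = default_centroids(k),
                             target_freqs = default_target_freqs(k),
                             w_dist = 0.5, w_freq = 0.5,
                             length_scale = 1, emission_sd = 0.2,
                             n_blocks = 7388L, coupling = 0,
                             seed = 1L,
                             feature_means = c(0.08, 0.08, 0.08),
                             feature_sds = c(0.04, 0.04, 0.04)) {
  k <- as.integer(k)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != k) stop("`centroids` must have k rows", call. = FALSE)
  if (anyDuplicated(centroids)) {
    stop("`centroids` must be pairwise distinct", call. = FALSE)
  }
  if (length(target_freqs) != k || any(target_freqs < 0) ||
      abs(sum(target_freqs) - 1) > 1e-9) {
    stop("`target_freqs` must be a length-k probability vector",
         call. = FALSE)
  }
  if (w_dist < 0 || w_freq < 0 || w_dist + w_freq <= 0) {
    stop("weights must be non-negative and not both zero", call. = FALSE)
  }
  if (length_scale <= 0) stop("`length_scale` must be positive", call. = FALSE)
  if (emission_sd < 0) stop("`emission_sd` must be non-negative", call. = FALSE)
  if (coupling < 0 || coupling > 1) stop("`coupling` must be in [0, 1]",
                                         call. = FALSE)
  structure(
    list(k = k, centroids = centroids, target_freqs = target_freqs,
         w_dist = w_dist, w_freq = w_freq, length_scale = length_scale,
         emission_sd = emission_sd, n_blocks = as.integer(n_blocks),
         coupling = coupling, seed = as.integer(seed),
         feature_means = feature_means, feature_sds = feature_sds),
    class = "generator_config"
  )
}

#' Deterministic sub-seed derivation
#'
#' Splits one user-facing seed into reproducible sub-seeds for the
#' independent stochastic stages of a simulation, via a
#' linear-congruential step modulo 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param i stage index (1, 2, ...).
#' @return Integer sub-seed in 1..(2^31 - 2).
#' @export
derive_seed <- function(seed, i) {
  as.integer((48271 * (as.numeric(seed) + i) + 11) %% 2147483646 + 1)
}

#' Ground-truth transition matrix of a generator
#'
#' @param config a `generator_config`.
#' @return An `mtm` whose `probs` rows are exactly stochastic; `counts`
#'   is zero (the matrix is a law, not an estimate).
#' @export
build_generator_matrix <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  d <- centroid_distances(config$centroids)
  f <- config$target_freqs
  raw <- config$w_freq * outer(f, f) +
    config$w_dist * exp(-d / config$length_scale)
  rs <- rowSums(raw)
  if (any(rs == 0)) stop("configuration yields an all-zero row", call. = FALSE)
  probs <- raw / rs
  structure(
    list(k = config$k, counts = matrix(0L, config$k, config$k),
         probs = probs, subject_id = "generator", role = "law"),
    class = "mtm"
  )
}

#' Sample a Markov chain of states
#'
#' @param T an `mtm` (or plain row-stochastic matrix) defining the law.
#' @param n_blocks number of steps (>= 2).
#' @param seed RNG seed.
#' @param init_probs initial-state distribution (default uniform over
#'   states with defined rows).
#' @param init_state optional fixed initial state (overrides
#'   `init_probs`).
#' @return Integer label vector of length `n_blocks`.
#' @export
simulate_states <- function(T, n_blocks, seed = 1L, init_probs = NULL,
                            init_state = NULL) {
  probs <- if (inherits(T, "mtm")) T$probs else as.matrix(T)
  k <- nrow(probs)
  if (n_blocks < 2L) stop("`n_blocks` must be at least 2", call. = FALSE)
  defined <- which(!is.na(probs[, 1L]))
  bad <- abs(rowSums(probs[defined, , drop = FALSE]) - 1) > 1e-9
  if (any(bad)) stop("rows are not stochastic", call. = FALSE)
  cum <- probs
  cum[defined, ] <- t(apply(probs[defined, , drop = FALSE], 1L, cumsum))
  set.seed(seed)
  out <- integer(n_blocks)
  if (!is.null(init_state)) {
    out[1L] <- as.integer(init_state)
  } else {
    if (is.null(init_probs)) {
      init_probs <- numeric(k); init_probs[defined] <- 1 / length(defined)
    }
    out[1L] <- sample.int(k, 1L, prob = init_probs)
  }
  u <- stats::runif(n_blocks - 1L)
  for (t in seq(2L, n_blocks)) {
    s <- out[t - 1L]
    if (is.na(cum[s, 1L])) {
      stop("chain entered a state with an undefined row: ", s, call. = FALSE)
    }
    out[t] <- min(k, findInterval(u[t - 1L], cum[s, ], left.open = TRUE) + 1L)
  }
  out
}

#' Emit word-block features from state sequences
#'
#' Inverts the clustering step: each block's speaker features are the
#' state centroid plus Gaussian noise in standardized space, mapped back
#' to the \[0, 1\] relative-frequency scale via the configured
#' per-feature mean/sd and clipped to \[0, 1\]. The clipping rate is
#' attached as attribute `clip_rate`; above 5% a warning is raised.
#'
#' @param pat_states,ther_states equal-length integer state sequences.
#' @param config_pat patient `generator_config` (centroids, noise,
#'   back-transform).
#' @param config_ther therapist config (defaults to `config_pat`).
#' @param seed RNG seed for the emission noise.
#' @return A validated block-series tibble with attribute `clip_rate`.
#' @export
emit_blocks <- function(pat_states, ther_states, config_pat,
                        config_ther = config_pat, seed = 1L) {
  if (length(pat_states) != length(ther_states)) {
    stop("state sequences must have equal length", call. = FALSE)
  }
  emit_one <- function(states, config) {
    z <- config$centroids[states, , drop = FALSE]
    if (config$emission_sd > 0) {
      z <- z + matrix(stats::rnorm(length(z), 0, config$emission_sd),
                      nrow(z), ncol(z))
    }
    raw <- sweep(sweep(z, 2L, config$feature_sds, "*"), 2L,
                 config$feature_means, "+")
    clipped <- pmin(pmax(raw, 0), 1)
    list(x = clipped, n_clip = sum(raw < 0 | raw > 1))
  }
  set.seed(seed)
  p <- emit_one(pat_states, config_pat)
  h <- emit_one(ther_states, config_ther)
  series <- tibble::tibble(
    t = seq_along(pat_states) - 1L,
    pat_pos = p$x[, 1L], pat_neg = p$x[, 2L], pat_abs = p$x[, 3L],
    ther_pos = h$x[, 1L], ther_neg = h$x[, 2L], ther_abs = h$x[, 3L]
  )
  clip_rate <- (p$n_clip + h$n_clip) / (length(pat_states) * 6)
  if (clip_rate > 0.05) {
    warning(sprintf("%.1f%% of emitted features were clipped to [0, 1]",
                    100 * clip_rate), call. = FALSE)
  }
  series <- validate_block_series(series)
  attr(series, "clip_rate") <- clip_rate
  series
}

#' Simulate a coupled patient-therapist dyad
#'
#' The patient's states follow the patient config's transition law. At
#' each block the therapist copies a deterministic map of the patient's
#' state with probability `kappa` (the coupling), and otherwise advances
#' by one step of the therapist's own chain. `kappa = 0` gives
#' independent chains; `kappa = 1` a fully driven therapist. Sub-seeds
#' for the patient chain, the therapist chain, the coupling coin-flips
#' and the emission noise are derived deterministically from `seed` via
#' [derive_seed()].
#'
#' @param config_pat,config_ther `generator_config`s sharing `n_blocks`.
#' @param coupling overrides `config_pat$coupling` when not `NULL`.
#' @param seed base seed (defaults to `config_pat$seed`).
#' @param state_map deterministic patient-to-therapist state map
#'   (integer vector of length k; default identity).
#' @return A list with `pat_states`, `ther_states` (`state_sequence`s),
#'   `series` (block-series tibble), `truth` (generator matrices,
#'   configs and the map).
#' @export
simulate_dyad <- function(config_pat, config_ther = config_pat,
                          coupling = NULL, seed = NULL,
                          state_map = seq_len(config_ther$k)) {
  if (config_pat$n_blocks != config_ther$n_blocks) {
    stop("configs disagree on `n_blocks`", call. = FALSE)
  }
  kappa <- coupling %||% config_pat$coupling
  if (kappa < 0 || kappa > 1) stop("`coupling` must be in [0, 1]",
                                   call. = FALSE)
  seed <- seed %||% config_pat$seed
  n <- config_pat$n_blocks
  T_pat <- build_generator_matrix(config_pat)
  T_ther <- build_generator_matrix(config_ther)
  pat <- simulate_states(T_pat, n, seed = derive_seed(seed, 1L),
                         init_probs = config_pat$target_freqs)
  # therapist's own chain, then overwrite coupled blocks
  ther <- simulate_states(T_ther, n, seed = derive_seed(seed, 2L),
                          init_probs = config_ther$target_freqs)
  if (kappa > 0) {
    set.seed(derive_seed(seed, 3L))
    copy <- stats::runif(n) < kappa
    ther[copy] <- state_map[pat[copy]]
  }
  series <- emit_blocks(pat, ther, config_pat, config_ther,
                        seed = derive_seed(seed, 4L))
  list(
    pat_states = state_sequence(pat, role = "patient",
                                active_states = seq_len(config_pat$k)),
    ther_states = state_sequence(ther, role = "therapist",
                                 active_states = seq_len(config_ther$k)),
    series = series,
    truth = list(T_pat = T_pat, T_ther = T_ther, config_pat = config_pat,
                 config_ther = config_ther, coupling = kappa,
                 state_map = state_map)
  )
}

#' Stationary distribution of a transition matrix
#'
#' Left-eigenvector solve for the stationary distribution of an ergodic
#' chain; used to report target vs. realized state frequencies side by
#' side (in general they differ).
#'
#' @param T an `mtm` or row-stochastic matrix (all rows defined).
#' @return Length-k probability vector.
#' @export
stationary_distribution <- function(T) {
  probs <- if (inherits(T, "mtm")) T$probs else as.matrix(T)
  if (anyNA(probs)) stop("all rows must be defined", call. = FALSE)
  e <- eigen(t(probs))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Write / read a generator configuration
#'
#' Plain-text (JSON) serialization that round-trips losslessly.
#'
#' @param config a `generator_config`.
#' @param path file path.
#' @return `path` / the restored `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    k = x$k, centroids = matrix(unlist(x$centroids), nrow = x$k),
    target_freqs = x$target_freqs, w_dist = x$w_dist, w_freq = x$w_freq,
    length_scale = x$length_scale, emission_sd = x$emission_sd,
    n_blocks = x$n_blocks, coupling = x$coupling, seed = x$seed,
    feature_means = unlist(x$feature_means),
    feature_sds = unlist(x$feature_sds)
  )
}
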