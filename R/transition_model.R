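#' Pairwise Euclidean distances between state centroids
#'
#' @param model a `cluster_model`, or a numeric centroid matrix (states
#'   in rows, standardized features in columns).
#' @return Symmetric k x k distance matrix with zero diagonal.
#' @export
centroid_distances <- function(model) {
  centroids <- if (inherits(model, "cluster_model")) model$centroids else
    as.matrix(model)
  d <- as.matrix(stats::dist(centroids, method = "euclidean"))
  dimnames(d) <- list(seq_len(nrow(centroids)), seq_len(nrow(centroids)))
  d
}

#' Assemble the transition-law design table
#'
#' One row per retained MTM cell (i, j): the transition probability as
#' response, with the Euclidean centroid distance `d_ij`, the
#' destination-state relative frequency `f_j`, and the composite
#' frequency `f_i * f_j` as candidate regressors. Only cells whose row
#' is defined and whose source and destination states are both active
#' enter; the diagonal is included by default (self-transitions are
#' transitions of the matrix like any other).
#'
#' @param T an `mtm`.
#' @param distances k x k centroid distance matrix.
#' @param frequencies length-k relative state frequencies (computed from
#'   the same pruned sequence that generated `T`).
#' @param active_states states to retain (default: states with defined
#'   rows in `T`).
#' @param include_diagonal keep i == j cells (default TRUE).
#' @return A tibble with columns `i`, `j`, `y`, `x_dist`, `x_freqj`,
#'   `x_comp`.
#' @export
build_design <- function(T, distances, frequencies, active_states = NULL,
                         include_diagonal = TRUE) {
  if (is.null(active_states)) active_states <- which(rowSums(T$counts) > 0)
  active_states <- intersect(active_states, which(rowSums(T$counts) > 0))
  grid <- expand.grid(i = active_states, j = active_states)
  if (!include_diagonal) grid <- grid[grid$i != grid$j, , drop = FALSE]
  if (nrow(grid) < 5L) stop("fewer than 5 design cells", call. = FALSE)
  tibble::tibble(
    i = grid$i, j = grid$j,
    y = T$probs[cbind(grid$i, grid$j)],
    x_dist = distances[cbind(grid$i, grid$j)],
    x_freqj = frequencies[grid$j],
    x_comp = frequencies[grid$i] * frequencies[grid$j]
  )
}

mode_regressors <- list(
  distance = "x_dist",
  freq_j = "x_freqj",
  composite = "x_comp",
  full = c("x_dist", "x_comp")
)

#' Fit one transition-law regression mode
#'
#' Ordinary least squares of the z-scored transition probabilities on
#' z-scored regressors, so the coefficients are standardized betas. The
#' four modes correspond to candidate transition laws: `distance`
#' (transitions fall off with inter-state distance), `freq_j`
#' (destination-frequency-dependent, the fully ergodic law),
#' `composite` (product of source and destination frequencies, the
#' random-walk law), and `full` (distance + composite, the best-fitting
#' two-regressor law).
#'
#' @param design a design tibble from [build_design()].
#' @param mode one of `"distance"`, `"freq_j"`, `"composite"`, `"full"`.
#' @param subject_id,role metadata carried on the result.
#' @return One-row tibble: `mode`, `beta_dist`, `beta_comp`,
#'   `beta_freqj`, `r`, `r2`, `adj_r2`, `p_model`, `beta_ratio`
#'   (`|beta_comp| / |beta_dist|`, full mode only; `NA` when
#'   `beta_dist` is 0), `n_cells`, `k_predictors`.
#' @export
fit_model <- function(design, mode = c("full", "distance", "freq_j", "composite"),
                      subject_id = NA_character_, role = NA_character_) {
  mode <- match.arg(mode)
  regs <- mode_regressors[[mode]]
  if (stats::sd(design$y) == 0) stop("zero variance in y", call. = FALSE)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  zd <- data.frame(y = zs(design$y))
  for (rg in regs) {
    if (stats::sd(design[[rg]]) == 0) {
      stop("zero variance in regressor ", rg, call. = FALSE)
    }
    zd[[rg]] <- zs(design[[rg]])
  }
  if (length(regs) == 2L &&
      abs(stats::cor(zd[[regs[1L]]], zd[[regs[2L]]])) >= 1 - 1e-12) {
    stop("collinear regressors", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(regs, "y"), data = zd)
  coefs <- stats::coef(fit)[regs]
  n <- nrow(zd)
  k <- length(regs)
  r2 <- summary(fit)$r.squared
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  fstat <- summary(fit)$fstatistic
  p_model <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  beta_dist <- unname(coefs["x_dist"])
  beta_comp <- unname(coefs["x_comp"])
  beta_ratio <- if (mode == "full") {
    if (beta_dist == 0) NA_real_ else abs(beta_comp) / abs(beta_dist)
  } else NA_real_
  tibble::tibble(
    subject_id = subject_id, role = role, mode = mode,
    beta_dist = if (is.null(beta_dist)) NA_real_ else beta_dist,
    beta_comp = if (is.null(beta_comp)) NA_real_ else beta_comp,
    beta_freqj = unname(coefs["x_freqj"]) %||% NA_real_,
    r = sqrt(r2), r2 = r2, adj_r2 = adj_r2,
    p_model = unname(p_model), beta_ratio = beta_ratio,
    n_cells = n, k_predictors = k
  )
}

#' Compare the candidate transition laws on one subject
#'
#' Fits all four regression modes on the same design and ranks them by
#' adjusted R^2.
#'
#' @inheritParams fit_model
#' @param T,distances,frequencies passed to [build_design()] when
#'   `design` is not supplied directly.
#' @param ... passed to [build_design()].
#' @return Tibble of [fit_model()] rows, ranked by descending `adj_r2`
#'   with a `rank` column.
#' @export
compare_modes <- function(T, distances, frequencies,
                          subject_id = NA_character_, role = NA_character_,
                          ...) {
  design <- build_design(T, distances, frequencies, ...)
  out <- do.call(rbind, lapply(names(mode_regressors), function(m) {
    fit_model(design, m, subject_id = subject_id, role = role)
  }))
  out <- out[order(-out$adj_r2), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Cohort summary of transition-law fits by role
#'
#' Arithmetic (signed) means of the per-subject standardized betas and
#' fit statistics within each role, plus the cross-role
#' distance-dependence ratio: the absolute value of one role's mean
#' `beta_dist` over the other's, quantifying how much more strongly one
#' role's transitions depend on inter-state distance.
#'
#' @param results tibble of [fit_model()] rows with a `role` column.
#' @param ratio_roles length-2 character: numerator and denominator
#'   roles for the cross-role ratio (default patient over therapist).
#' @return A list with `by_role` (one summary row per role) and
#'   `cross_role_dist_ratio`.
#' @export
cohort_summary <- function(results, ratio_roles = c("patient", "therapist")) {
  roles <- unique(results$role)
  if (length(roles) == 0L) stop("empty results", call. = FALSE)
  by_role <- do.call(rbind, lapply(roles, function(rl) {
    d <- results[results$role == rl, , drop = FALSE]
    tibble::tibble(
      role = rl, n_subjects = nrow(d),
      beta_dist = mean(d$beta_dist), beta_comp = mean(d$beta_comp),
      r = mean(d$r), r2 = mean(d$r2), adj_r2 = mean(d$adj_r2),
      beta_ratio = mean(d$beta_ratio)
    )
  }))
  ratio <- NA_real_
  if (all(ratio_roles %in% by_role$role)) {
    num <- abs(by_role$beta_dist[by_role$role == ratio_roles[1L]])
    den <- abs(by_role$beta_dist[by_role$role == ratio_roles[2L]])
    ratio <- num / den
  }
  list(by_role = by_role, cross_role_dist_ratio = ratio)
}
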