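#' Ordered categorical state sequence
#'
#' Holds the symbolic dynamic of one speaker (or dyad): an ordered vector
#' of state labels over `1..k`, together with the original block indices
#' `t` (so sequences from the two roles can be re-aligned after pruning)
#' and the indices of blocks removed by pruning.
#'
#' @param labels integer state labels.
#' @param role `"patient"`, `"therapist"` or `"dyad"`.
#' @param subject_id subject identifier.
#' @param t original block indices (defaults to `0:(n-1)`).
#' @param active_states states the labels may take (defaults to observed).
#' @param dropped_indices original indices removed by pruning.
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(labels, role = "patient", subject_id = "subject",
                           t = NULL, active_states = NULL,
                           dropped_indices = integer()) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers", call. = FALSE)
  if (is.null(t)) t <- seq_along(labels) - 1L
  if (length(t) != length(labels)) {
    stop("`t` must match `labels` in length", call. = FALSE)
  }
  if (is.null(active_states)) active_states <- sort(unique(labels))
  if (!all(labels %in% active_states)) {
    stop("labels outside `active_states`", call. = FALSE)
  }
  if (!role %in% c("patient", "therapist", "dyad")) {
    stop("`role` must be patient, therapist or dyad", call. = FALSE)
  }
  structure(
    list(labels = labels, role = role, subject_id = subject_id,
         t = as.integer(t), active_states = as.integer(active_states),
         dropped_indices = as.integer(dropped_indices)),
    class = "state_sequence"
  )
}

#' @export
length.state_sequence <- function(x) length(x$labels)

#' @export
print.state_sequence <- function(x, ...) {
  cat("<state_sequence> ", x$subject_id, " (", x$role, "): ",
      length(x$labels), " blocks, states {",
      paste(x$active_states, collapse = ","), "}, ",
      length(x$dropped_indices), " pruned\n", sep = "")
  invisible(x)
}

#' Z-score feature columns
#'
#' Standardizes each feature column to mean 0, sd 1 over the training
#' data, or applies previously stored constants to new data. Cluster
#' centroids are interpreted in this standardized space, where e.g. a
#' "silence" state shows a negative sign on all three dictionaries.
#'
#' @param x numeric matrix or data frame of features (blocks in rows).
#' @param constants optional list with `means` and `sds` from a previous
#'   call; when supplied they are applied unchanged.
#' @return A list with `z` (standardized matrix), `means`, `sds`.
#' @export
standardize_features <- function(x, constants = NULL) {
  x <- as.matrix(x)
  if (is.null(constants)) {
    if (nrow(x) < 2L) stop("need at least 2 blocks", call. = FALSE)
    means <- colMeans(x)
    sds <- apply(x, 2L, stats::sd)
    zero <- which(sds == 0 | !is.finite(sds))
    if (length(zero) > 0L) {
      nm <- colnames(x)[zero[1L]]
      stop("zero-variance column: ",
           if (is.null(nm)) zero[1L] else nm, call. = FALSE)
    }
  } else {
    means <- constants$means
    sds <- constants$sds
  }
  z <- sweep(sweep(x, 2L, means, "-"), 2L, sds, "/")
  list(z = z, means = means, sds = sds)
}

#' Extract one role's feature matrix from a block series
#'
#' @param series a validated block-series table.
#' @param role `"patient"` or `"therapist"`.
#' @return Numeric matrix with columns `pos`, `neg`, `abs`.
#' @export
role_features <- function(series, role = c("patient", "therapist")) {
  role <- match.arg(role)
  pre <- if (role == "patient") "pat_" else "ther_"
  m <- as.matrix(series[, paste0(pre, c("pos", "neg", "abs"))])
  colnames(m) <- c("pos", "neg", "abs")
  m
}

kmeanspp_centers <- function(z, k) {
  # D^2-weighted seeding: start from a random point, then draw each new
  # center with probability proportional to the squared distance to the
  # nearest center chosen so far; scarce far-out clusters are seeded
  # almost surely, which plain random restarts miss
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  centers[1L, ] <- z[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(z, 2L, centers[1L, ], "-")^2)
  for (j in seq(2L, k)) {
    pick <- sample.int(n, 1L, prob = d2 + 1e-300)
    centers[j, ] <- z[pick, ]
    d2 <- pmin(d2, rowSums(sweep(z, 2L, centers[j, ], "-")^2))
  }
  centers
}

#' Fit k-means states to standardized features
#'
#' Runs multi-restart k-means with D^2-weighted (k-means++) seeding and
#' keeps the best solution by total within-cluster sum of squares.
#' States are relabelled 1..k by descending occupancy (ties broken by
#' the original cluster index), so the labelling is deterministic given
#' the seed and state 1 is always the most visited.
#'
#' @param z standardized feature matrix (from [standardize_features()]).
#' @param k number of states (default 8).
#' @param n_restarts seeded restarts (default 50).
#' @param seed RNG seed.
#' @param constants standardization constants to store with the model.
#' @param role role tag stored with the model.
#' @return An object of class `cluster_model` with fields `role`, `k`,
#'   `feature_means`, `feature_sds`, `centroids` (k x p, standardized
#'   space), `occupancy`, `variance_explained`, `active_states`,
#'   `labels` (training labels after relabelling).
#' @export
fit_states <- function(z, k = 8L, n_restarts = 50L, seed = 1L,
                       constants = NULL, role = "patient") {
  z <- as.matrix(z)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (nrow(z) < k) stop("fewer rows than states", call. = FALSE)
  if (nrow(unique(z)) < k) {
    stop("`k` exceeds the number of distinct rows", call. = FALSE)
  }
  set.seed(seed)
  uz <- unique(z)
  if (nrow(uz) == k) {
    # exactly k distinct rows: the perfect partition, no iteration needed
    labels0 <- match(
      apply(z, 1L, paste, collapse = "\r"),
      apply(uz, 1L, paste, collapse = "\r")
    )
    km <- list(cluster = labels0, centers = uz,
               size = tabulate(labels0, k),
               betweenss = sum(sweep(uz[labels0, , drop = FALSE], 2L,
                                     colMeans(z), "-")^2),
               totss = sum(sweep(z, 2L, colMeans(z), "-")^2),
               tot.withinss = 0)
    if (km$totss == 0) km$betweenss <- km$totss
    ord <- order(km$size, seq_len(k), decreasing = c(TRUE, FALSE),
                 method = "radix")
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    centroids <- km$centers[ord, , drop = FALSE]
    rownames(centroids) <- seq_len(k)
    return(structure(
      list(role = role, k = k,
           feature_means = constants$means, feature_sds = constants$sds,
           centroids = centroids,
           occupancy = as.integer(km$size[ord]),
           variance_explained = if (km$totss == 0) 1 else
             km$betweenss / km$totss,
           active_states = seq_len(k),
           labels = relabel[km$cluster]),
      class = "cluster_model"
    ))
  }
  km <- NULL
  for (r in seq_len(n_restarts)) {
    cand <- tryCatch(
      suppressWarnings(
        stats::kmeans(z, centers = kmeanspp_centers(z, k), iter.max = 100L)
      ),
      error = function(e) NULL
    )
    if (!is.null(cand) &&
        (is.null(km) || cand$tot.withinss < km$tot.withinss)) {
      km <- cand
    }
  }
  if (is.null(km)) stop("k-means failed on every restart", call. = FALSE)
  # relabel by descending occupancy; ties keep the original cluster order
  ord <- order(km$size, seq_len(k), decreasing = c(TRUE, FALSE),
               method = "radix")
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  occupancy <- as.integer(km$size[ord])
  structure(
    list(
      role = role, k = k,
      feature_means = constants$means, feature_sds = constants$sds,
      centroids = centroids, occupancy = occupancy,
      variance_explained = km$betweenss / km$totss,
      active_states = seq_len(k),
      labels = labels
    ),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> role=", x$role, " k=", x$k,
      " variance explained=", round(x$variance_explained, 3),
      " active={", paste(x$active_states, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Between-cluster share of total sum of squares
#'
#' Recomputes the fraction of variance explained by a cluster model on a
#' given standardized data set: 1 - WCSS/TSS, with TSS around the grand
#' mean of `z`.
#'
#' @param model a `cluster_model`.
#' @param z standardized feature matrix with matching columns.
#' @param labels state labels for the rows of `z` (defaults to nearest
#'   centroid assignment).
#' @return Fraction in \[0, 1\].
#' @export
variance_explained <- function(model, z, labels = NULL) {
  z <- as.matrix(z)
  if (is.null(labels)) labels <- nearest_state(z, model$centroids)
  centers <- model$centroids[labels, , drop = FALSE]
  wcss <- sum((z - centers)^2)
  tss <- sum(sweep(z, 2L, colMeans(z), "-")^2)
  if (tss == 0) return(1)
  1 - wcss / tss
}

nearest_state <- function(z, centroids) {
  # squared Euclidean distance to each centroid; ties -> lowest label
  d2 <- outer(rowSums(z^2), rowSums(centroids^2), "+") -
    2 * z %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Prune scarcely populated states
#'
#' States whose occupancy share over the supplied sequence falls below
#' `min_share` are treated as outliers: they are removed from the active
#' state set and every block labelled with them is deleted. Survivors
#' are re-concatenated, so a transition can span a deletion; use
#' [count_transitions()]'s `breaks` argument to instead break the chain
#' at deletions.
#'
#' @param model a `cluster_model`.
#' @param seq a `state_sequence` labelled with the model's states.
#' @param min_share minimum occupancy share to survive (default 0.01).
#' @return A list with `model` (reduced `active_states`) and `seq`
#'   (pruned `state_sequence` with `dropped_indices` recorded).
#' @export
prune_outlier_states <- function(model, seq, min_share = 0.01) {
  stopifnot(inherits(model, "cluster_model"), inherits(seq, "state_sequence"))
  share <- tabulate(seq$labels, nbins = model$k) / length(seq$labels)
  keep_states <- which(share >= min_share)
  if (length(keep_states) == 0L) {
    stop("pruning removed every state; lower `min_share`", call. = FALSE)
  }
  keep <- seq$labels %in% keep_states
  model$active_states <- as.integer(keep_states)
  pruned <- state_sequence(
    labels = seq$labels[keep], role = seq$role, subject_id = seq$subject_id,
    t = seq$t[keep], active_states = as.integer(keep_states),
    dropped_indices = c(seq$dropped_indices, seq$t[!keep])
  )
  list(model = model, seq = pruned)
}

#' Serialize a cluster model to JSON
#'
#' Stores the standardization constants, centroids, occupancy and active
#' state set; `read_cluster_model()` restores a model usable with
#' [assign_states()].
#'
#' @param model a `cluster_model`.
#' @param path file path.
#' @return `path` / the restored `cluster_model`.
#' @export
write_cluster_model <- function(model, path) {
  payload <- list(
    role = model$role, k = model$k,
    feature_means = model$feature_means, feature_sds = model$feature_sds,
    centroids = model$centroids, occupancy = model$occupancy,
    variance_explained = model$variance_explained,
    active_states = model$active_states
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- matrix(unlist(x$centroids), nrow = x$k)
  rownames(centroids) <- seq_len(x$k)
  structure(
    list(role = x$role, k = as.integer(x$k),
         feature_means = unlist(x$feature_means),
         feature_sds = unlist(x$feature_sds),
         centroids = centroids, occupancy = as.integer(x$occupancy),
         variance_explained = x$variance_explained,
         active_states = as.integer(x$active_states), labels = NULL),
    class = "cluster_model"
  )
}

#' Write / read state sequences as a long CSV
#'
#' One row per retained block: `t`, `subject_id`, `role`, `state`.
#' Reading back regroups rows into one `state_sequence` per
#' subject-role combination (dropped indices are not preserved).
#'
#' @param sequences list of `state_sequence` objects.
#' @param path file path.
#' @param active_states active state set to attach on read (defaults to
#'   the states observed per sequence).
#' @return `path` / a list of `state_sequence` objects.
#' @export
write_state_sequences <- function(sequences, path) {
  rows <- do.call(rbind, lapply(sequences, function(s) {
    data.frame(t = s$t, subject_id = s$subject_id, role = s$role,
               state = s$labels, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_sequences
#' @export
read_state_sequences <- function(path, active_states = NULL) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  parts <- split(rows, interaction(rows$subject_id, rows$role, drop = TRUE))
  out <- lapply(parts, function(p) {
    p <- p[order(p$t), , drop = FALSE]
    state_sequence(p$state, role = p$role[1L], subject_id = p$subject_id[1L],
                   t = p$t,
                   active_states = active_states %||% sort(unique(p$state)))
  })
  names(out) <- vapply(out, function(s) paste(s$subject_id, s$role, sep = "."),
                       "")
  out
}

#' Restrict a sequence to a set of active states
#'
#' Drops every block labelled with a state outside `states` (recording
#' the dropped original indices) and re-concatenates the survivors.
#' Used when the pruning decision is made on pooled data and then
#' applied to each subject's sequence.
#'
#' @param seq a `state_sequence`.
#' @param states integer vector of states to keep.
#' @return A pruned `state_sequence`.
#' @export
restrict_to_states <- function(seq, states) {
  stopifnot(inherits(seq, "state_sequence"))
  keep <- seq$labels %in% states
  if (!any(keep)) stop("no blocks left after restriction", call. = FALSE)
  state_sequence(
    labels = seq$labels[keep], role = seq$role, subject_id = seq$subject_id,
    t = seq$t[keep], active_states = as.integer(states),
    dropped_indices = c(seq$dropped_indices, seq$t[!keep])
  )
}

#' Assign blocks to states by nearest centroid
#'
#' Maps each block of a series to its nearest centroid in standardized
#' space (Euclidean distance; ties broken by the lowest state label).
#' On the training data this reproduces the fitted labels.
#'
#' @param series a block-series table, or a raw feature matrix already
#'   on the original scale.
#' @param model a `cluster_model` holding standardization constants.
#' @param role which speaker's features to use when `series` is a
#'   block-series table (defaults to the model's role).
#' @param subject_id subject identifier for the returned sequence.
#' @return A `state_sequence` over the model's full state set.
#' @export
assign_states <- function(series, model, role = NULL, subject_id = "subject") {
  if (is.null(role)) role <- model$role
  x <- if (is.matrix(series)) series else role_features(series, role)
  if (ncol(x) != ncol(model$centroids)) {
    stop("feature count mismatch with model centroids", call. = FALSE)
  }
  z <- standardize_features(
    x, constants = list(means = model$feature_means, sds = model$feature_sds)
  )$z
  state_sequence(nearest_state(z, model$centroids), role = role,
                 subject_id = subject_id,
                 active_states = seq_len(model$k))
}
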