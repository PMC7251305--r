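#' Count one-step transitions
#'
#' Builds the k x k count matrix of one-step transitions of a state
#' sequence: `counts[i, j]` is the number of times state `i` is followed
#' by state `j`. The matrix is kept at the full pre-pruning size `k`, so
#' matrices from different subjects share one index space; rows of
#' states never visited simply stay empty.
#'
#' @param seq a `state_sequence` or an integer label vector.
#' @param k state-space size.
#' @param breaks optional positions after which the chain is broken
#'   (pairs spanning a break are not counted). By default pruned blocks
#'   are spliced out and transitions may span a deletion.
#' @return k x k integer matrix of counts.
#' @export
count_transitions <- function(seq, k, breaks = integer()) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
  if (length(labels) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(labels < 1L | labels > k)) {
    stop("labels outside 1..k", call. = FALSE)
  }
  from <- labels[-length(labels)]
  to <- labels[-1L]
  if (length(breaks) > 0L) {
    keep <- !(seq_along(from) %in% breaks)
    from <- from[keep]; to <- to[keep]
  }
  counts <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  for (idx in seq_along(from)) {
    counts[from[idx], to[idx]] <- counts[from[idx], to[idx]] + 1L
  }
  counts
}

#' First-order Markov transition matrix
#'
#' Row-normalizes the transition counts into conditional probabilities
#' `P(X_{t+1} = j | X_t = i)`. Rows with no observed departures (states
#' never visited, e.g. pruned states) are undefined and stored as `NA`,
#' never as zeros.
#'
#' @param seq a `state_sequence` or integer label vector.
#' @param k state-space size.
#' @param subject_id,role metadata carried on the result (taken from
#'   `seq` when it is a `state_sequence`).
#' @return An object of class `mtm` with fields `k`, `counts`, `probs`,
#'   `subject_id`, `role`.
#' @export
mtm <- function(seq, k, subject_id = NULL, role = NULL) {
  if (inherits(seq, "state_sequence")) {
    if (is.null(subject_id)) subject_id <- seq$subject_id
    if (is.null(role)) role <- seq$role
  }
  counts <- count_transitions(seq, k)
  mtm_from_counts(counts, subject_id = subject_id %||% "subject",
                  role = role %||% "patient")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an `mtm` from a count matrix
#'
#' @param counts non-negative integer matrix (square, or rectangular for
#'   dyad matrices whose rows and columns index different roles).
#' @param subject_id,role metadata.
#' @return An `mtm` object; `k` is the row dimension.
#' @export
mtm_from_counts <- function(counts, subject_id = "subject", role = "patient") {
  counts <- as.matrix(counts)
  rowsum <- rowSums(counts)
  probs <- counts / rowsum
  probs[rowsum == 0, ] <- NA_real_
  structure(
    list(k = nrow(counts), counts = counts, probs = probs,
         subject_id = subject_id, role = role),
    class = "mtm"
  )
}

#' @export
print.mtm <- function(x, digits = 3, ...) {
  cat("<mtm> ", x$subject_id, " (", x$role, "): ",
      nrow(x$counts), "x", ncol(x$counts), ", ",
      sum(x$counts), " transitions, defined rows: ",
      sum(rowSums(x$counts) > 0), "\n", sep = "")
  print(round(x$probs, digits))
  invisible(x)
}

#' Relative state frequencies of a sequence
#'
#' @param seq a `state_sequence` or integer label vector.
#' @param k state-space size.
#' @return Length-k vector of occurrence counts divided by sequence
#'   length; sums to 1.
#' @export
state_frequencies <- function(seq, k) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
  if (length(labels) == 0L) stop("empty sequence", call. = FALSE)
  tabulate(labels, nbins = k) / length(labels)
}

#' Interleaved dyad transition pairs
#'
#' Builds the cross-speaker transition pairs of the interleaved dyadic
#' dynamic Pat(1), Ther(1), Pat(2), Ther(2), ... Sequences are aligned
#' on the block indices `t` surviving pruning in *both* roles.
#' `direction = "P2T"` pairs the patient's state with the therapist's
#' state of the same block; `"T2P"` pairs the therapist's state with the
#' patient's state of the next aligned block.
#'
#' @param pat,ther `state_sequence` objects for the two roles.
#' @param direction `"P2T"` or `"T2P"`.
#' @return Integer matrix with columns `from`, `to`, one row per pair.
#' @export
dyad_sequence <- function(pat, ther, direction = c("P2T", "T2P")) {
  direction <- match.arg(direction)
  stopifnot(inherits(pat, "state_sequence"), inherits(ther, "state_sequence"))
  common <- intersect(pat$t, ther$t)
  if (length(common) == 0L) stop("no aligned blocks", call. = FALSE)
  common <- sort(common)
  p <- pat$labels[match(common, pat$t)]
  h <- ther$labels[match(common, ther$t)]
  if (direction == "P2T") {
    cbind(from = p, to = h)
  } else {
    if (length(common) < 2L) stop("no aligned consecutive pairs", call. = FALSE)
    cbind(from = h[-length(h)], to = p[-1L])
  }
}

#' Dyadic Markov transition matrix
#'
#' Estimates the cross-speaker transition matrix from dyad pairs, with
#' rows indexed by the source role's state space and columns by the
#' target role's. With `interleaved_chain = TRUE` the full interleaved
#' sequence Pat(1), Ther(1), Pat(2), ... is instead treated as a single
#' chain over one shared state space, and both within- and cross-speaker
#' steps enter the counts.
#'
#' @param pat,ther `state_sequence` objects.
#' @param k state-space size (rows and columns).
#' @param direction `"P2T"` or `"T2P"`.
#' @param interleaved_chain treat the interleaving as one chain.
#' @return An `mtm` with `role` set to the direction.
#' @export
dyad_mtm <- function(pat, ther, k, direction = c("P2T", "T2P"),
                     interleaved_chain = FALSE) {
  direction <- match.arg(direction)
  if (interleaved_chain) {
    common <- sort(intersect(pat$t, ther$t))
    if (length(common) == 0L) stop("no aligned blocks", call. = FALSE)
    p <- pat$labels[match(common, pat$t)]
    h <- ther$labels[match(common, ther$t)]
    inter <- as.vector(rbind(p, h))
    if (direction == "T2P") inter <- inter[-1L]
    return(mtm(inter, k, subject_id = pat$subject_id,
               role = paste0(direction, "_chain")))
  }
  pairs <- dyad_sequence(pat, ther, direction)
  if (any(pairs < 1L | pairs > k)) stop("labels outside 1..k", call. = FALSE)
  counts <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  for (idx in seq_len(nrow(pairs))) {
    counts[pairs[idx, 1L], pairs[idx, 2L]] <-
      counts[pairs[idx, 1L], pairs[idx, 2L]] + 1L
  }
  mtm_from_counts(counts, subject_id = pat$subject_id, role = direction)
}

#' Flag the highest-probability transition of each row
#'
#' @param T an `mtm`.
#' @return Logical matrix; for each defined row, `TRUE` on every cell
#'   attaining the row maximum (ties are all flagged).
#' @export
row_max_flags <- function(T) {
  probs <- T$probs
  flags <- matrix(FALSE, nrow(probs), ncol(probs), dimnames = dimnames(probs))
  for (i in seq_len(nrow(probs))) {
    if (all(is.na(probs[i, ]))) next
    m <- max(probs[i, ], na.rm = TRUE)
    flags[i, ] <- !is.na(probs[i, ]) & abs(probs[i, ] - m) < 1e-12
  }
  flags
}

#' Export a transition matrix as a weighted directed network
#'
#' Writes the nonzero transitions as a weighted directed edge list in
#' DOT or GraphML, one edge per nonzero cell with attributes
#' `probability`, `count` and `is_row_max` (the highest-probability
#' transition of each state; ties all flagged).
#'
#' @param T an `mtm`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param min_weight drop edges with probability below this threshold.
#' @return The edge table (source, target, probability, count,
#'   is_row_max), invisibly.
#' @export
export_network <- function(T, path, format = c("dot", "graphml"),
                           min_weight = 0) {
  format <- match.arg(format)
  probs <- T$probs
  flags <- row_max_flags(T)
  idx <- which(!is.na(probs) & probs > 0 & probs >= min_weight,
               arr.ind = TRUE)
  edges <- data.frame(
    from = idx[, 1L], to = idx[, 2L],
    probability = probs[idx], count = T$counts[idx],
    is_row_max = as.integer(flags[idx]) # 0/1: DOT has no boolean attrs
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = seq_len(max(nrow(probs), ncol(probs))))
  )
  igraph::E(g)$weight <- edges$probability
  igraph::write_graph(g, path, format = format)
  invisible(edges)
}

#' Write a transition matrix as CSV with blank undefined rows
#'
#' Mirrors the conventional printed layout: undefined rows (states never
#' visited) are left blank rather than written as zeros.
#'
#' @param T an `mtm`.
#' @param path output file.
#' @param digits rounding for probabilities (default 3).
#' @return `path`, invisibly.
#' @export
write_mtm_csv <- function(T, path, digits = 3L) {
  m <- formatC(round(T$probs, digits), format = "g")
  m[is.na(T$probs)] <- ""
  df <- data.frame(state = seq_len(nrow(m)), m, check.names = FALSE)
  colnames(df) <- c("state", seq_len(ncol(m)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
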