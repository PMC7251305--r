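#' Split a state sequence into first and last thirds
#'
#' Takes the leading and trailing `floor(n/3)` labels; the middle is
#' discarded, so the two segments always have equal length.
#'
#' @param seq a `state_sequence` or integer label vector.
#' @return A list with `first`, `last` (label vectors) and `n1`, `n2`
#'   (their equal lengths).
#' @export
split_thirds <- function(seq) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
  n <- length(labels)
  if (n < 6L) stop("sequence too short to split into thirds", call. = FALSE)
  m <- n %/% 3L
  list(first = labels[seq_len(m)], last = labels[seq(n - m + 1L, n)],
       n1 = m, n2 = m)
}

#' Odds-ratio drift test for one state
#'
#' Compares the occupancy of one state between two segments of a
#' treatment via the 2x2 table `((a, n1-a), (b, n2-b))`, where `a` and
#' `b` count the state's occurrences in each segment. Reports the odds
#' ratio `a (n2-b) / (b (n1-a))`, its 95% CI by the log-OR normal
#' approximation, and a chi-square p-value (Yates-corrected by default;
#' `"none"` and `"fisher"` are available). A zero cell leaves the OR and
#' CI undefined unless `haldane = TRUE`, which adds 0.5 to every cell
#' for the OR/CI only (never silently).
#'
#' @param first,last label vectors for the two segments.
#' @param state state whose occupancy is tested.
#' @param correction `"yates"` (default), `"none"` or `"fisher"`.
#' @param haldane apply the Haldane-Anscombe +0.5 correction to the
#'   OR/CI when a zero cell occurs.
#' @return One-row tibble: `state`, `a`, `n1`, `b`, `n2`, `odds_ratio`,
#'   `or_ci_lower`, `or_ci_upper`, `chi2`, `p_value`, `correction`.
#' @export
state_drift_test <- function(first, last, state,
                             correction = c("yates", "none", "fisher"),
                             haldane = FALSE) {
  correction <- match.arg(correction)
  n1 <- length(first); n2 <- length(last)
  if (n1 == 0L || n2 == 0L) stop("empty segment", call. = FALSE)
  a <- sum(first == state); b <- sum(last == state)
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2L, byrow = TRUE)
  cells <- as.numeric(tab)
  if (any(cells == 0) && haldane) cells <- cells + 0.5
  if (any(cells == 0)) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    or <- (cells[1L] * cells[4L]) / (cells[3L] * cells[2L])
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1.96, 1.96) * se)
  }
  if (correction == "fisher") {
    chi2 <- NA_real_
    p <- stats::fisher.test(tab)$p.value
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(tab, correct = correction == "yates")
    )
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  tibble::tibble(
    state = state, a = a, n1 = n1, b = b, n2 = n2,
    odds_ratio = or, or_ci_lower = ci[1L], or_ci_upper = ci[2L],
    chi2 = chi2, p_value = p, correction = correction
  )
}

#' Drift screen over all active states
#'
#' Runs [state_drift_test()] for every active state of a sequence,
#' comparing its first and last third. Raw p-values are flagged at
#' `alpha` (mirroring a per-state screen without multiplicity
#' adjustment) and a Benjamini-Hochberg-adjusted column is always
#' emitted alongside.
#'
#' @param seq a `state_sequence` (or label vector with `states` given).
#' @param states states to screen (default: the sequence's active set).
#' @param alpha flagging level for raw p-values (default 0.05).
#' @param subject_id,role metadata columns (taken from `seq` when
#'   available).
#' @inheritParams state_drift_test
#' @return Tibble with one row per state: the [state_drift_test()]
#'   columns plus `p_bh` and `flagged`.
#' @export
drift_screen <- function(seq, states = NULL, alpha = 0.05,
                         correction = "yates", haldane = FALSE,
                         subject_id = NULL, role = NULL) {
  if (inherits(seq, "state_sequence")) {
    if (is.null(states)) states <- seq$active_states
    if (is.null(subject_id)) subject_id <- seq$subject_id
    if (is.null(role)) role <- seq$role
  }
  if (is.null(states)) states <- sort(unique(as.integer(seq)))
  halves <- split_thirds(seq)
  out <- do.call(rbind, lapply(states, function(s) {
    state_drift_test(halves$first, halves$last, s,
                     correction = correction, haldane = haldane)
  }))
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- out$p_value < alpha
  tibble::add_column(out,
                     subject_id = subject_id %||% NA_character_,
                     role = role %||% NA_character_, .before = 1L)
}
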