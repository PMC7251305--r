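#' Pearson correlation between two transition matrices
#'
#' Correlates the linearized cells of two MTMs sharing one index space.
#' Under the default `"both_defined"` policy, only cells from rows
#' defined in *both* matrices enter; structurally undefined rows are
#' excluded rather than imputed as zeros. `"union_zero"` instead treats
#' undefined rows as zeros and uses all k^2 cells, for sensitivity
#' analysis.
#'
#' @param A,B `mtm` objects with equal dimensions.
#' @param cell_policy `"both_defined"` (default) or `"union_zero"`.
#' @return Pearson r.
#' @export
mtm_correlation <- function(A, B, cell_policy = c("both_defined", "union_zero")) {
  cell_policy <- match.arg(cell_policy)
  pa <- A$probs; pb <- B$probs
  if (!all(dim(pa) == dim(pb))) {
    stop("matrices are not on the same index space", call. = FALSE)
  }
  if (cell_policy == "both_defined") {
    rows <- rowSums(A$counts) > 0 & rowSums(B$counts) > 0
    a <- as.vector(pa[rows, , drop = FALSE])
    b <- as.vector(pb[rows, , drop = FALSE])
  } else {
    pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
    a <- as.vector(pa); b <- as.vector(pb)
  }
  if (length(a) < 3L) stop("fewer than 3 comparable cells", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in linearized cells", call. = FALSE)
  }
  stats::cor(a, b)
}

#' DeltaCorr between two dyads
#'
#' The patient-side minus therapist-side similarity of two
#' psychotherapeutic dyads:
#' `DeltaCorr(i, j) = CorrPat(i, j) - CorrTher(i, j)`, where each term
#' is the Pearson correlation between the corresponding speakers'
#' transition matrices. Positive values mean the two patients' dynamics
#' resemble each other more than their therapists' do.
#'
#' @param pat_i,pat_j the two patients' `mtm`s.
#' @param ther_i,ther_j the two therapists' `mtm`s.
#' @param pair length-2 character vector naming the dyads.
#' @param class outcome-pair class label, e.g. `"poor-poor"`,
#'   `"good-good"`, `"poor-good"`.
#' @param cell_policy passed to [mtm_correlation()].
#' @return A one-row tibble with `pair_i`, `pair_j`, `corr_pat`,
#'   `corr_ther`, `delta`, `class`.
#' @export
delta_corr <- function(pat_i, pat_j, ther_i, ther_j,
                       pair = c(pat_i$subject_id, pat_j$subject_id),
                       class = NA_character_,
                       cell_policy = "both_defined") {
  if (identical(pair[1L], pair[2L])) {
    stop("DeltaCorr needs two distinct dyads", call. = FALSE)
  }
  corr_pat <- mtm_correlation(pat_i, pat_j, cell_policy)
  corr_ther <- mtm_correlation(ther_i, ther_j, cell_policy)
  tibble::tibble(
    pair_i = pair[1L], pair_j = pair[2L],
    corr_pat = corr_pat, corr_ther = corr_ther,
    delta = corr_pat - corr_ther, class = class
  )
}

#' Summary of a value by outcome class with normal-approximation CI
#'
#' Mean, sample standard deviation, range and the 95% confidence
#' interval `mean +/- 1.96 * sd / sqrt(n)` of a set of records'
#' `value_col`, restricted to one class.
#'
#' @param records tibble with a `class` column and the value column.
#' @param class class to summarise.
#' @param value_col column to summarise (default `"delta"`).
#' @return One-row tibble: `class`, `n`, `mean`, `sd`, `min`, `max`,
#'   `ci_lower`, `ci_upper`.
#' @export
class_summary <- function(records, class, value_col = "delta") {
  x <- records[[value_col]][records$class == class]
  n <- length(x)
  if (n < 2L) stop("need at least 2 records in class '", class, "'",
                   call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  half <- 1.96 * s / sqrt(n)
  tibble::tibble(
    class = class, n = n, mean = m, sd = s, min = min(x), max = max(x),
    ci_lower = m - half, ci_upper = m + half
  )
}

#' Pairwise correlation panel over a set of transition matrices
#'
#' All unordered pairwise Pearson correlations among a list of MTMs on
#' one index space, with the mean and standard deviation over the upper
#' triangle.
#'
#' @param mats list of `mtm` objects.
#' @param cell_policy passed to [mtm_correlation()].
#' @return A list with `r` (symmetric matrix, unit diagonal), `mean`,
#'   `sd` (over distinct pairs), and `pairs` (long tibble).
#' @export
correlation_panel <- function(mats, cell_policy = "both_defined") {
  n <- length(mats)
  if (n < 2L) stop("need at least 2 matrices", call. = FALSE)
  ids <- vapply(mats, function(m) m$subject_id, character(1))
  r <- diag(1, n)
  dimnames(r) <- list(ids, ids)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rij <- mtm_correlation(mats[[i]], mats[[j]], cell_policy)
      r[i, j] <- r[j, i] <- rij
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_i = ids[i], subject_j = ids[j], r = rij
      )
    }
  }
  pairs <- do.call(rbind, rows)
  list(r = r, mean = mean(pairs$r), sd = stats::sd(pairs$r), pairs = pairs)
}
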