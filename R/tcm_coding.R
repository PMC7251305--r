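#' Dictionary set for word-block coding
#'
#' Bundles the three coding dictionaries used to score transcript
#' word-blocks: positive emotional tone (POS), negative emotional tone
#' (NEG), and abstraction (AB). Entries must be lowercase single tokens
#' and the three lists must be pairwise disjoint, so that per-block
#' relative frequencies of the three categories can never sum above 1.
#'
#' @param pos_words character vector of positive-tone words.
#' @param neg_words character vector of negative-tone words.
#' @param abs_words character vector of abstraction words.
#' @return An object of class `dictionary_set`.
#' @examples
#' dictionary_set(c("happy", "agree"), c("sad", "abandon"), c("year", "soul"))
#' @export
dictionary_set <- function(pos_words, neg_words, abs_words) {
  dicts <- list(pos = pos_words, neg = neg_words, abs = abs_words)
  for (nm in names(dicts)) {
    w <- dicts[[nm]]
    if (length(w) == 0L) {
      stop("dictionary '", nm, "' is empty", call. = FALSE)
    }
    if (!is.character(w)) {
      stop("dictionary '", nm, "' must be a character vector", call. = FALSE)
    }
    if (any(w != tolower(w))) {
      stop("dictionary '", nm, "' contains non-lowercase entries", call. = FALSE)
    }
    if (any(grepl("\\s", w))) {
      stop("dictionary '", nm, "' contains entries with whitespace", call. = FALSE)
    }
    dicts[[nm]] <- unique(w)
  }
  overlap <- c(
    intersect(dicts$pos, dicts$neg),
    intersect(dicts$pos, dicts$abs),
    intersect(dicts$neg, dicts$abs)
  )
  if (length(overlap) > 0L) {
    stop(
      "dictionaries must be pairwise disjoint; overlapping entries: ",
      paste(unique(overlap), collapse = ", "),
      call. = FALSE
    )
  }
  structure(dicts, class = "dictionary_set")
}

#' Speaker-attributed token stream
#'
#' Builds the token table feeding block segmentation. Tokens are
#' lowercased; the caller is responsible for tokenization (no stemming
#' is applied). Positions are global word indices and must be strictly
#' increasing.
#'
#' @param token character vector of words.
#' @param speaker character vector, each `"patient"` or `"therapist"`.
#' @param position optional integer vector of strictly increasing global
#'   word indices; defaults to `seq_along(token) - 1`.
#' @return A `data.frame` with columns `token`, `speaker`, `position`.
#' @export
speaker_tokens <- function(token, speaker, position = NULL) {
  if (length(token) == 0L) stop("no input: empty token stream", call. = FALSE)
  if (length(speaker) != length(token)) {
    stop("`token` and `speaker` must have equal length", call. = FALSE)
  }
  if (!all(speaker %in% c("patient", "therapist"))) {
    stop("`speaker` entries must be 'patient' or 'therapist'", call. = FALSE)
  }
  if (is.null(position)) position <- seq_along(token) - 1L
  if (any(diff(position) <= 0L)) {
    stop("`position` must be strictly increasing", call. = FALSE)
  }
  data.frame(
    token = tolower(token), speaker = speaker, position = as.integer(position),
    stringsAsFactors = FALSE
  )
}

#' Segment a token stream into fixed-size word-blocks
#'
#' Cuts the stream into consecutive, non-overlapping blocks of exactly
#' `block_size` tokens, in original order. A trailing remainder shorter
#' than `block_size` is dropped, so every block shares the same
#' denominator when scored.
#'
#' @param tokens a token table from [speaker_tokens()].
#' @param block_size tokens per block (default 150).
#' @return A list of token tables, one per block.
#' @examples
#' toks <- speaker_tokens(rep("word", 10), rep("patient", 10))
#' length(segment_blocks(toks, 3)) # 3 blocks; token 10 dropped
#' @export
segment_blocks <- function(tokens, block_size = 150L) {
  if (is.null(tokens) || nrow(tokens) == 0L) {
    stop("no input: empty token stream", call. = FALSE)
  }
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) {
    stop("`block_size` must be a positive integer", call. = FALSE)
  }
  n_blocks <- nrow(tokens) %/% block_size
  if (n_blocks == 0L) return(list())
  idx <- rep(seq_len(n_blocks), each = block_size)
  kept <- tokens[seq_len(n_blocks * block_size), , drop = FALSE]
  unname(split(kept, idx))
}

#' Score word-blocks against the three dictionaries
#'
#' For each block and each speaker, computes the relative frequency of
#' dictionary hits: (number of that speaker's tokens in the block that
#' match the dictionary) / `block_size`. The denominator is the full
#' block size, not the speaker's word count, so a silent speaker scores
#' (0, 0, 0). Matching is exact string equality after lowercasing.
#'
#' @param blocks list of token tables from [segment_blocks()].
#' @param dicts a [dictionary_set()].
#' @return A block-series tibble with columns `t`, `pat_pos`, `pat_neg`,
#'   `pat_abs`, `ther_pos`, `ther_neg`, `ther_abs`.
#' @export
code_blocks <- function(blocks, dicts) {
  stopifnot(inherits(dicts, "dictionary_set"))
  if (length(blocks) == 0L) stop("no input: empty block list", call. = FALSE)
  block_size <- nrow(blocks[[1L]])
  score <- function(blk) {
    stopifnot(nrow(blk) == block_size)
    tok <- tolower(blk$token)
    pat <- blk$speaker == "patient"
    c(
      pat_pos = sum(pat & tok %in% dicts$pos),
      pat_neg = sum(pat & tok %in% dicts$neg),
      pat_abs = sum(pat & tok %in% dicts$abs),
      ther_pos = sum(!pat & tok %in% dicts$pos),
      ther_neg = sum(!pat & tok %in% dicts$neg),
      ther_abs = sum(!pat & tok %in% dicts$abs)
    ) / block_size
  }
  feats <- do.call(rbind, lapply(blocks, score))
  out <- tibble::as_tibble(as.data.frame(feats))
  out <- tibble::add_column(out, t = seq_len(nrow(out)) - 1L, .before = 1L)
  validate_block_series(out)
}

block_feature_cols <- c(
  "pat_pos", "pat_neg", "pat_abs", "ther_pos", "ther_neg", "ther_abs"
)

#' Validate a word-block series table
#'
#' Checks the block-series invariants: all six feature columns present
#' and numeric, every feature in \[0, 1\], within each speaker
#' pos + neg + abs <= 1, and block index `t` strictly increasing.
#' Violations are reported with the offending row.
#'
#' @param series a data frame with columns `t` and the six features.
#' @return The validated series as a tibble (invisibly the same data).
#' @export
validate_block_series <- function(series) {
  missing <- setdiff(c("t", block_feature_cols), names(series))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("t", block_feature_cols)) {
    v <- series[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", col, "' at row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing value in column '", col, "' at row ",
           which(is.na(v))[1L], call. = FALSE)
    }
  }
  for (col in block_feature_cols) {
    v <- series[[col]]
    bad <- which(v < 0 | v > 1)
    if (length(bad) > 0L) {
      stop("feature '", col, "' outside [0, 1] at row ", bad[1L],
           call. = FALSE)
    }
  }
  for (role in c("pat", "ther")) {
    tot <- series[[paste0(role, "_pos")]] + series[[paste0(role, "_neg")]] +
      series[[paste0(role, "_abs")]]
    bad <- which(tot > 1 + 1e-9)
    if (length(bad) > 0L) {
      stop("speaker '", role, "' dictionary frequencies sum above 1 at row ",
           bad[1L], call. = FALSE)
    }
  }
  if (nrow(series) > 1L && any(diff(series$t) <= 0)) {
    stop("block index `t` must be strictly increasing (row ",
         which(diff(series$t) <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  tibble::as_tibble(series)
}

#' Read a word-block series from delimited text
#'
#' Columns are matched by header name, so column order in the file is
#' irrelevant. The series is validated on load; violations are rejected
#' with the offending row and column.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return A validated block-series tibble.
#' @export
load_block_series <- function(path, delim = ",") {
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  keep <- c("t", intersect(block_feature_cols, names(raw)))
  validate_block_series(raw[, intersect(keep, names(raw)), drop = FALSE])
}

#' Write a word-block series to delimited text
#'
#' @param series a validated block-series table.
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_block_series <- function(series, path, delim = ",") {
  series <- validate_block_series(series)
  utils::write.table(series[, c("t", block_feature_cols)], path,
                     sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
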