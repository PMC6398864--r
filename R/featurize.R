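# Bag-of-words featurization of free-text notes over the pre-exposure
# lookback window.

#' Normalize free text into tokens
#'
#' Cleaning rules, applied in order: lowercase; strip special characters
#' (anything that is not a letter, digit, or whitespace); split on
#' whitespace; drop empty tokens and tokens not starting with a letter or a
#' digit; drop stop words. Token order is preserved. Digit-initial tokens
#' ("500mg") are kept.
#'
#' @param raw character vector of raw note texts
#' @param stop_words character vector of lowercase stop words
#' @return list of character vectors, one per input string
#' @export
#' @examples
#' normalize_text("De Maagpijn!! #ernstig", stop_words = "de")
normalize_text <- function(raw, stop_words = default_stopwords()) {
  if (length(raw) == 0) return(list())
  tf <- tokenize_flat(raw, stop_words)
  out <- vector("list", length(raw))
  out[] <- list(character(0))
  if (length(tf$idx)) {
    sp <- split(tf$token, factor(tf$idx, levels = seq_along(raw)))
    out <- unname(sp)
  }
  out
}

# Vectorized core of normalize_text: returns the surviving tokens of a text
# vector as a flat (source index, token) pair, avoiding per-document lists.
tokenize_flat <- function(raw, stop_words) {
  x <- tolower(raw)
  x <- gsub("[^\\p{L}\\p{N}\\s]+", "", x, perl = TRUE)
  toks <- strsplit(trimws(x), "\\s+")
  flat <- unlist(toks, use.names = FALSE)
  idx <- rep.int(seq_along(raw), lengths(toks))
  keep <- nzchar(flat) & !(flat %in% stop_words)
  # post-strip, tokens start with a letter or digit; check the rule on the
  # unique values only (cheap defensive guard)
  ut <- unique(flat[keep])
  bad <- ut[!grepl("^[\\p{L}\\p{N}]", ut, perl = TRUE)]
  if (length(bad)) keep <- keep & !(flat %in% bad)
  list(idx = idx[keep], token = flat[keep])
}

#' Default stop-word list
#'
#' Dutch articles and a few high-frequency function words, shipped as a
#' plain-text file (one word per line); injectable everywhere it is used.
#'
#' @return character vector of lowercase stop words
#' @export
default_stopwords <- function() {
  f <- system.file("extdata", "stopwords_nl.txt", package = "textps")
  if (nzchar(f)) readLines(f, encoding = "UTF-8") else c("de", "het", "een")
}

#' Build the episode-by-word bag-of-words matrix
#'
#' For each episode, tokens are pooled from every note of that patient dated
#' in the half-open lookback window `[start - lookback_days, start)`. Cells
#' are binary presence by default (count mode behind the `binary` flag).
#' Words occurring in zero episodes are dropped; episodes with no in-window
#' notes keep an all-zero row.
#'
#' @param episodes episode table from [build_episodes()]
#' @param notes notes table (`patient_id`, `date`, `text`)
#' @param stop_words stop-word vector passed to [normalize_text()]
#' @param lookback_days length of the lookback window in days
#' @param binary presence (TRUE) or token counts (FALSE)
#' @return a `feature_matrix`: sparse matrix with episode ids as row names
#'   and words as column names, plus `lookback_days` and `binary` attributes
#' @export
build_bow <- function(episodes, notes, stop_words = default_stopwords(),
                      lookback_days = 183L, binary = TRUE) {
  assert_that(nrow(episodes) > 0, "episodes must be nonempty")
  ep <- data.table::as.data.table(episodes)
  nt <- data.table::as.data.table(notes)
  if (nrow(nt) > 0) {
    nt <- nt[, list(patient_id, note_date = as_date_safe(date), text)]
    win <- ep[, list(episode_id, patient_id,
                     win_lo = start_date - lookback_days,
                     win_hi = start_date)]
    hits <- nt[win, on = list(patient_id, note_date >= win_lo,
                              note_date < win_hi),
               list(episode_id = i.episode_id, text = x.text),
               nomatch = NULL, allow.cartesian = TRUE]
  } else {
    hits <- data.table::data.table(episode_id = character(0),
                                   text = character(0))
  }

  if (nrow(hits) > 0) {
    tf <- tokenize_flat(hits$text, stop_words)
    pairs <- data.table::data.table(
      episode_id = hits$episode_id[tf$idx],
      token = tf$token
    )
  } else {
    pairs <- data.table::data.table(episode_id = character(0),
                                    token = character(0))
  }

  ep_ids <- ep$episode_id
  if (nrow(pairs) > 0) {
    tally <- pairs[, list(n = .N), by = list(episode_id, token)]
    labels <- sort(unique(tally$token))
    m <- Matrix::sparseMatrix(
      i = match(tally$episode_id, ep_ids),
      j = match(tally$token, labels),
      x = if (binary) rep(1, nrow(tally)) else as.numeric(tally$n),
      dims = c(length(ep_ids), length(labels)),
      dimnames = list(ep_ids, labels)
    )
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(ep_ids), 0L),
                              dimnames = list(ep_ids, character(0)))
  }
  feature_matrix(m, lookback_days = lookback_days, binary = binary)
}

#' Construct a feature matrix object
#'
#' Thin S3 wrapper around a sparse (dgCMatrix) episode-by-covariate matrix
#' with episode ids as row names and covariate labels as column names.
#'
#' @param m matrix or Matrix with dimnames set
#' @param lookback_days lookback window used to build it (metadata)
#' @param binary TRUE when cells are 0/1 presence
#' @return a `feature_matrix`
#' @export
feature_matrix <- function(m, lookback_days = NA_integer_, binary = TRUE) {
  m <- methods::as(methods::as(methods::as(
    Matrix::Matrix(m, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  assert_that(!is.null(rownames(m)), "feature matrix needs row names")
  assert_that(!anyDuplicated(colnames(m)), "duplicate covariate labels")
  assert_that(all(m@x >= 0), "feature values must be nonnegative")
  structure(list(m = m, lookback_days = lookback_days, binary = binary),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d episodes x %d covariates (%s, lookback %s days), fill %.4f\n",
    nrow(x$m), ncol(x$m), if (x$binary) "binary" else "counts",
    format(x$lookback_days),
    if (prod(dim(x$m)) > 0) length(x$m@x) / prod(dim(x$m)) else 0
  ))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$m)

#' Episode ids of a feature matrix
#' @param fm a `feature_matrix`
#' @return character vector
#' @export
episode_ids <- function(fm) rownames(fm$m)

#' Covariate labels of a feature matrix
#' @param fm a `feature_matrix`
#' @return character vector
#' @export
covariate_labels <- function(fm) colnames(fm$m)

#' Document frequency of each covariate
#'
#' Number of episodes in which each covariate is present (nonzero). In
#' binary mode this equals the column sums.
#'
#' @param fm a `feature_matrix`
#' @return named integer vector
#' @export
doc_freq <- function(fm) {
  df <- Matrix::colSums(fm$m > 0)
  stats::setNames(as.integer(df), colnames(fm$m))
}

#' Restrict a feature matrix to a subset of covariates
#' @param fm a `feature_matrix`
#' @param labels covariate labels to keep (order respected)
#' @return a `feature_matrix`
#' @export
select_covariates <- function(fm, labels) {
  missing <- setdiff(labels, colnames(fm$m))
  assert_that(length(missing) == 0,
              paste("unknown covariate labels:",
                    paste(utils::head(missing, 5), collapse = ", ")))
  feature_matrix(fm$m[, labels, drop = FALSE],
                 lookback_days = fm$lookback_days, binary = fm$binary)
}

#' Write a feature matrix as MatrixMarket plus label sidecars
#'
#' Writes `<stem>.mtx` (sparse matrix), `<stem>.rows` (episode ids) and
#' `<stem>.cols` (covariate labels).
#'
#' @param fm a `feature_matrix`
#' @param stem path stem (no extension)
#' @return the stem, invisibly
#' @export
write_feature_matrix <- function(fm, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(fm$m, paste0(stem, ".mtx"))
  writeLines(rownames(fm$m), paste0(stem, ".rows"))
  writeLines(colnames(fm$m), paste0(stem, ".cols"))
  invisible(stem)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param stem path stem (no extension)
#' @param lookback_days,binary metadata to attach
#' @return a `feature_matrix`
#' @export
read_feature_matrix <- function(stem, lookback_days = NA_integer_,
                                binary = TRUE) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  dimnames(m) <- list(readLines(paste0(stem, ".rows")),
                      readLines(paste0(stem, ".cols")))
  feature_matrix(m, lookback_days = lookback_days, binary = binary)
}
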