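# Data model for item-level survey responses and the answered / skipped /
# dropped cell semantics every downstream stage consumes.

#' Construct a response matrix
#'
#' A `response_matrix` holds one row per subject and one column per analyzed
#' item (in survey order), with a binary indicator of whether the subject
#' answered the item. Subjects who answered no item at all never "started"
#' the survey (nonresponse, not dropout) and are excluded at construction,
#' with the excluded count recorded in the `n_excluded` attribute and
#' reported via a message.
#'
#' @param answered numeric/logical matrix (subjects x items) of 0/1
#'   indicators; no missing values.
#' @param subject_ids character vector of unique subject identifiers
#'   (default `s1..sN`).
#' @param item_labels character vector of item labels in survey order.
#'   Items are indexed by their position in the analyzed sequence; labels
#'   preserve the instrument's original names (e.g. `Q1, Q2, Q4, ...` when
#'   conditional items were excluded upstream).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(answered, subject_ids = NULL, item_labels = NULL) {
  answered <- as.matrix(answered)
  if (anyNA(answered)) data_error("answered matrix contains missing values")
  storage.mode(answered) <- "integer"
  if (!all(answered %in% c(0L, 1L))) {
    data_error("answered matrix must contain only 0/1")
  }
  n <- nrow(answered); p <- ncol(answered)
  if (p < 1L) data_error("response matrix needs at least one item")
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) data_error("duplicate subject ids")
  if (length(subject_ids) != n) data_error("subject_ids length does not match matrix")
  if (is.null(item_labels)) item_labels <- paste0("item_", seq_len(p))
  item_labels <- as.character(item_labels)
  if (length(item_labels) != p) data_error("item_labels length does not match matrix")

  started <- rowSums(answered) > 0L
  n_excluded <- sum(!started)
  if (n_excluded > 0L) {
    message(sprintf("Excluding %d subject(s) with zero answered items (never started)",
                    n_excluded))
    answered <- answered[started, , drop = FALSE]
    subject_ids <- subject_ids[started]
  }
  dimnames(answered) <- list(subject_ids, item_labels)
  structure(
    list(subject_ids = subject_ids, item_labels = item_labels,
         answered = answered,
         n_subjects = nrow(answered), n_items = p),
    n_excluded = n_excluded, class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Survey response matrix: %d subjects x %d items\n",
              x$n_subjects, x$n_items))
  cat(sprintf("  items: %s\n", paste(x$item_labels, collapse = ", ")))
  cs <- classify_cells(x)
  cat(sprintf("  completers: %d (%.1f%%); excluded non-starters: %d\n",
              sum(cs$completer), 100 * mean(cs$completer),
              attr(x, "n_excluded") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

.default_answered_codes <- c("1", "yes", "y", "true", "t", "answered")
.default_missing_codes  <- c("0", "no", "n", "false", "f", "", "na", "nan", "missing")

.decode_answers <- function(x, answered_codes, missing_codes) {
  v <- tolower(trimws(as.character(x)))
  v[is.na(v)] <- ""
  out <- integer(length(v))
  is_ans <- v %in% tolower(answered_codes)
  is_mis <- v %in% tolower(missing_codes)
  bad <- !(is_ans | is_mis)
  if (any(bad)) {
    data_error("unknown response code(s): %s",
               paste(unique(v[bad]), collapse = ", "))
  }
  out[is_ans] <- 1L
  out
}

#' Load item-level responses from a delimited text file
#'
#' Two layouts are supported. `wide`: one row per subject, first column the
#' subject id, remaining columns the analyzed items in survey order.
#' `long`: columns `subject` (or `subject_id`), `item` (or `item_index`),
#' `answered`; (subject, item) combinations absent from the file are
#' treated as not answered. Conditional / branched items must be excluded
#' by the caller before loading; the item list is taken as given.
#'
#' @param path path to a CSV or TSV file (delimiter auto-detected from the
#'   extension unless `sep` is given).
#' @param layout `"wide"` or `"long"`.
#' @param answered_codes,missing_codes case-insensitive value sets decoded
#'   to answered (1) and not-answered (0); any other value is a data error
#'   naming the offending code.
#' @param sep field delimiter override.
#' @return A [response_matrix].
#' @export
load_responses <- function(path, layout = c("wide", "long"),
                           answered_codes = .default_answered_codes,
                           missing_codes = .default_missing_codes,
                           sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) format_error("file not found: %s", path)
  sep <- .delim_for(path, sep)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                      check.names = FALSE, quote = "\"", comment.char = ""),
    error = function(e) format_error("cannot parse %s: %s", path, conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) {
    format_error("file %s has no usable rows/columns", path)
  }

  if (layout == "wide") {
    ids <- as.character(df[[1L]])
    items <- colnames(df)[-1L]
    mat <- vapply(df[-1L], .decode_answers, integer(nrow(df)),
                  answered_codes = answered_codes, missing_codes = missing_codes)
    mat <- matrix(mat, nrow = nrow(df))
    response_matrix(mat, subject_ids = ids, item_labels = items)
  } else {
    nm <- tolower(colnames(df))
    sj <- which(nm %in% c("subject", "subject_id", "id"))[1L]
    it <- which(nm %in% c("item", "item_index", "question"))[1L]
    an <- which(nm %in% c("answered", "response", "value"))[1L]
    if (anyNA(c(sj, it, an))) {
      format_error("long layout requires subject, item_index and answered columns")
    }
    subj <- as.character(df[[sj]])
    item <- suppressWarnings(as.integer(df[[it]]))
    if (anyNA(item) || any(item < 1L)) {
      data_error("item_index must be positive integers")
    }
    if (anyDuplicated(paste(subj, item, sep = "\r"))) {
      data_error("duplicate (subject, item) pairs in long file")
    }
    y <- .decode_answers(df[[an]], answered_codes, missing_codes)
    ids <- unique(subj)
    p <- max(item)
    mat <- matrix(0L, nrow = length(ids), ncol = p,
                  dimnames = list(ids, NULL))
    mat[cbind(match(subj, ids), item)] <- y
    response_matrix(mat, subject_ids = ids,
                    item_labels = paste0("item_", seq_len(p)))
  }
}

#' Write a response matrix to a delimited file
#'
#' @param rm a [response_matrix].
#' @param path output path (`.csv` or `.tsv`).
#' @param layout `"wide"` or `"long"`.
#' @export
write_responses <- function(rm, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  sep <- .delim_for(path)
  if (layout == "wide") {
    df <- data.frame(subject_id = rm$subject_ids,
                     as.data.frame(rm$answered), check.names = FALSE)
    colnames(df) <- c("subject_id", rm$item_labels)
  } else {
    df <- data.frame(
      subject_id = rep(rm$subject_ids, times = rm$n_items),
      item_index = rep(seq_len(rm$n_items), each = rm$n_subjects),
      answered   = as.vector(rm$answered))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify every not-answered cell as a skip or a dropout
#'
#' For each subject, `last_answered` is the position of the last answered
#' item and `dropout_point = last_answered + 1` (which exceeds `n_items`
#' for completers). A not-answered cell strictly before `last_answered` is
#' a SKIP (the subject returned to answer a later item); every cell at or
#' after `dropout_point` is DROPPED. A subject who answered earlier items
#' but skipped the final one is indistinguishable from a dropout at
#' `last_answered + 1`; this trailing-skip ambiguity is unavoidable from
#' response indicators alone and its rate can be quantified with
#' [trailing_skip_misclassification_rate()].
#'
#' @param rm a [response_matrix].
#' @return A list of class `cell_states` with elements `states` (character
#'   matrix of `"answered"`, `"skipped"`, `"dropped"`), `last_answered`,
#'   `dropout_point`, `completer` (logical; answered the final item).
#' @export
classify_cells <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  a <- rm$answered
  p <- rm$n_items
  last_answered <- apply(a, 1L, function(r) max(which(r == 1L)))
  dropout_point <- last_answered + 1L
  states <- matrix("dropped", nrow = nrow(a), ncol = p, dimnames = dimnames(a))
  col <- matrix(rep(seq_len(p), each = nrow(a)), nrow = nrow(a))
  states[a == 1L] <- "answered"
  states[a == 0L & col < last_answered] <- "skipped"
  structure(
    list(states = states,
         last_answered = stats::setNames(as.integer(last_answered), rm$subject_ids),
         dropout_point = stats::setNames(as.integer(dropout_point), rm$subject_ids),
         completer = stats::setNames(last_answered == p, rm$subject_ids)),
    class = "cell_states")
}

#' Export cell states as a canonical long-form table
#'
#' @param rm a [response_matrix].
#' @param path optional CSV path; when given the table is also written.
#' @return Long data frame (subject_id, item_index, item_label, state),
#'   invisibly when written to `path`.
#' @export
export_cell_states <- function(rm, path = NULL) {
  cs <- classify_cells(rm)
  df <- data.frame(
    subject_id = rep(rm$subject_ids, times = rm$n_items),
    item_index = rep(seq_len(rm$n_items), each = rm$n_subjects),
    item_label = rep(rm$item_labels, each = rm$n_subjects),
    state      = as.vector(cs$states))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Load a subject covariate table
#'
#' Covariates live in a separate CSV keyed by `subject_id` (group labels
#' such as cohort or recruitment phase, demographics, and optionally a
#' binary downstream outcome). Rows not matching a subject in `rm` are
#' dropped with a warning.
#'
#' @param path CSV path with a `subject_id` column.
#' @param rm optional [response_matrix] used to align and filter rows.
#' @return Data frame of covariates.
#' @export
load_covariates <- function(path, rm = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) format_error("cannot parse %s: %s",
                                                 path, conditionMessage(e)))
  idc <- which(tolower(colnames(df)) %in% c("subject_id", "subject", "id"))[1L]
  if (is.na(idc)) format_error("covariate file needs a subject_id column")
  colnames(df)[idc] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (!is.null(rm)) df <- align_covariates(df, rm)
  df
}

align_covariates <- function(covs, rm) {
  keep <- covs$subject_id %in% rm$subject_ids
  if (any(!keep)) {
    warning(sprintf("dropping %d covariate row(s) with no matching subject",
                    sum(!keep)))
  }
  covs <- covs[keep, , drop = FALSE]
  missing <- setdiff(rm$subject_ids, covs$subject_id)
  if (length(missing) > 0L) {
    data_error("covariates missing for %d subject(s), e.g. %s",
               length(missing), missing[1L])
  }
  covs[match(rm$subject_ids, covs$subject_id), , drop = FALSE]
}
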