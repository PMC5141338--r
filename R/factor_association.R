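# Stage-3 contingency analyses: association of prior-item responses and
# subject attributes with dropout at the next item, and
# completer-vs-noncompleter comparisons on a downstream outcome.

.contingency <- function(tab, correct = FALSE, fisher_threshold = 5) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) data_error("counts must be nonnegative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) data_error("table is degenerate (constant margin)")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  min_exp <- min(expected)
  if (min_exp < fisher_threshold) {
    ft <- stats::fisher.test(tab)
    res <- list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value, method = "chi-square")
  }
  row_pcts <- round(100 * tab / rowSums(tab), 2)
  structure(c(list(table = tab, row_pcts = row_pcts, min_expected = min_exp,
                   correct = correct), res),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Contingency analysis (%s%s)\n", x$method,
              if (x$method == "chi-square" && x$correct) ", Yates-corrected" else ""))
  both <- matrix(sprintf("%d (%.2f%%)", x$table, x$row_pcts),
                 nrow = nrow(x$table), dimnames = dimnames(x$table))
  print(both, quote = FALSE)
  if (x$method == "chi-square") {
    cat(sprintf("  X-squared = %.4f, df = %d, p = %.4g (min expected %.2f)\n",
                x$statistic, x$df, x$p_value, x$min_expected))
  } else {
    cat(sprintf("  Fisher exact p = %.4g (min expected %.2f < 5)\n",
                x$p_value, x$min_expected))
  }
  invisible(x)
}

#' Association between the response given at one item and answering the next
#'
#' Cross-tabulates each subject's response category at item `q` against
#' whether the subject answered item `q_next`, and tests independence.
#' "Dropout at the next question" is operationalized as
#' `answered(q_next)`, so a subject who merely skipped `q_next` but
#' returned later counts as "No", exactly as a respondent-count analysis
#' would. Pearson's chi-square (no continuity correction by default) is
#' used when all expected counts are at least 5, otherwise Fisher's exact
#' test.
#'
#' @param rm a [response_matrix].
#' @param q item whose answer categories are the exposure.
#' @param responses vector (or factor) of response categories, one per
#'   subject in `rm` order; only subjects who answered `q` are used, and
#'   empty categories are dropped with a warning.
#' @param q_next the later item whose answering is the outcome.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return A `contingency_result`: counts, row percentages, statistic,
#'   df, p-value, method, and the smallest expected cell count.
#' @export
response_vs_next_dropout <- function(rm, q, responses, q_next, correct = FALSE) {
  stopifnot(inherits(rm, "response_matrix"))
  if (q_next <= q) config_error("q_next must come after q")
  if (q_next > rm$n_items) config_error("q_next exceeds the number of items")
  if (length(responses) != rm$n_subjects) {
    data_error("responses must have one entry per subject")
  }
  keep <- rm$answered[, q] == 1L
  if (any(is.na(responses[keep]))) {
    data_error("response category missing for a subject who answered item %d", q)
  }
  f <- factor(responses[keep])
  empty <- levels(f)[table(f) == 0L]
  if (length(empty) > 0L) {
    warning(sprintf("dropping empty categories: %s", paste(empty, collapse = ", ")))
    f <- droplevels(f)
  }
  ans <- factor(ifelse(rm$answered[keep, q_next] == 1L, "yes", "no"),
                levels = c("yes", "no"))
  .contingency(table(response = f, answered_next = ans), correct = correct)
}

#' Compare a binary downstream outcome between completers and noncompleters
#'
#' Tests whether survey completion is associated with a binary outcome
#' recorded outside the survey (e.g. whether the subject subsequently
#' obtained the screening test the survey addressed).
#'
#' @param rm a [response_matrix].
#' @param covariates covariate data frame containing `outcome`.
#' @param outcome name of a binary covariate column.
#' @param correct Yates correction flag (default FALSE).
#' @return A `contingency_result` for the 2x2 completion-by-outcome table.
#' @export
completer_outcome_test <- function(rm, covariates, outcome, correct = FALSE) {
  stopifnot(inherits(rm, "response_matrix"))
  covariates <- align_covariates(covariates, rm)
  if (!outcome %in% colnames(covariates)) config_error("unknown outcome '%s'", outcome)
  y <- covariates[[outcome]]
  if (anyNA(y)) data_error("outcome has missing values")
  if (length(unique(y)) < 2L) data_error("outcome is constant; table is degenerate")
  cs <- classify_cells(rm)
  comp <- factor(ifelse(cs$completer, "completer", "noncompleter"),
                 levels = c("completer", "noncompleter"))
  out <- factor(y)
  if (length(unique(comp)) < 2L) data_error("all subjects have the same completion status")
  .contingency(table(completion = comp, outcome = out), correct = correct)
}

#' Write a contingency result to CSV (counts and percentages side by side)
#' @param x a `contingency_result`.
#' @param path output CSV path.
#' @export
write_contingency_csv <- function(x, path) {
  df <- data.frame(
    row = rep(rownames(x$table) %||% seq_len(nrow(x$table)), ncol(x$table)),
    col = rep(colnames(x$table) %||% seq_len(ncol(x$table)), each = nrow(x$table)),
    count = as.vector(x$table), row_pct = as.vector(x$row_pcts))
  df$method <- x$method
  df$statistic <- x$statistic
  df$p_value <- x$p_value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
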