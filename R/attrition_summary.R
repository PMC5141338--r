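# Per-item attrition statistics: respondent/skip/dropout counts and
# percentages, and the three-phase (curiosity / attrition / stable)
# heuristic segmentation of the attrition curve.

#' Summarize attrition per item
#'
#' Builds the per-item attrition table: number and percentage of
#' respondents, skips, incremental dropouts (subjects whose dropout point
#' is that item) and cumulative dropouts. The denominator for every
#' percentage is the starter count (all loaded subjects), so the first
#' item plots at or near 100%; set `denominator = "previous"` for
#' conditional percentages relative to the previous item's respondents.
#'
#' At every item, `pct_respondents + pct_skips + pct_dropouts = 100` up to
#' rounding: each starter is, at a given item, exactly one of a
#' respondent, a skipper (not answered but answered later), or already
#' dropped.
#'
#' @param rm a [response_matrix].
#' @param covariates optional covariate data frame (see
#'   [load_covariates()]) used with `by_group`.
#' @param by_group optional name of a covariate column; when given, one
#'   table per group is returned (plus the pooled table), each using its
#'   group-specific starter count as denominator so unequal group sizes
#'   are adjusted for.
#' @param denominator `"starters"` (default) or `"previous"`.
#' @param digits decimal places for percentage columns (default 2).
#' @return A data frame of class `attrition_table` (or a named list of
#'   them with a `pooled` element when `by_group` is used) with columns
#'   `item`, `label`, `n_respondents`, `pct_respondents`, `n_skips`,
#'   `pct_skips`, `n_incremental_dropouts`, `n_cumulative_dropouts`,
#'   `pct_dropouts`. The starter count is kept in attribute `n_starters`.
#' @export
summarize_attrition <- function(rm, covariates = NULL, by_group = NULL,
                                denominator = c("starters", "previous"),
                                digits = 2) {
  denominator <- match.arg(denominator)
  if (is.null(by_group)) {
    return(.attrition_table(rm, denominator, digits))
  }
  if (is.null(covariates)) config_error("by_group requires a covariate table")
  covariates <- align_covariates(covariates, rm)
  if (!by_group %in% colnames(covariates)) {
    config_error("unknown covariate '%s'", by_group)
  }
  g <- as.factor(covariates[[by_group]])
  out <- lapply(levels(g), function(lev) {
    idx <- which(g == lev)
    sub <- response_matrix(rm$answered[idx, , drop = FALSE],
                           subject_ids = rm$subject_ids[idx],
                           item_labels = rm$item_labels)
    .attrition_table(sub, denominator, digits)
  })
  names(out) <- levels(g)
  out$pooled <- .attrition_table(rm, denominator, digits)
  out
}

.attrition_table <- function(rm, denominator = "starters", digits = 2) {
  cs <- classify_cells(rm)
  p <- rm$n_items
  n0 <- rm$n_subjects
  n_resp <- colSums(rm$answered)
  n_skip <- colSums(cs$states == "skipped")
  n_inc  <- tabulate(cs$dropout_point, nbins = p)  # dropout_point > p => completer
  n_cum  <- cumsum(n_inc)
  den <- if (denominator == "starters") rep(n0, p) else c(n0, n_resp[-p])
  pct <- function(x) round(100 * x / pmax(den, 1), digits)
  out <- data.frame(
    item = seq_len(p), label = rm$item_labels,
    n_respondents = as.integer(n_resp), pct_respondents = pct(n_resp),
    n_skips = as.integer(n_skip), pct_skips = pct(n_skip),
    n_incremental_dropouts = as.integer(n_inc),
    n_cumulative_dropouts = as.integer(n_cum),
    pct_dropouts = pct(n_cum),
    row.names = NULL)
  structure(out, n_starters = n0, denominator = denominator,
            class = c("attrition_table", "data.frame"))
}

#' Heuristic segmentation of the attrition curve into three phases
#'
#' Identifies the sigmoidal attrition pattern described by Eysenbach: a
#' curiosity plateau (high early response), an attrition phase (steep
#' decline), and a stable participation phase. The boundaries are found
#' from the per-item incremental dropout proportion: the curiosity
#' plateau ends just before the first item whose incremental dropout
#' proportion exceeds `threshold`; the attrition phase extends through the
#' maximal contiguous run of items above threshold, tolerating
#' single-item gaps; the stable rate is the mean respondent percentage
#' after the attrition phase. This is a heuristic mirror of a visual
#' judgement, not a changepoint inference, and is labeled as such.
#'
#' @param at an `attrition_table` (pooled).
#' @param threshold incremental dropout proportion (of starters) per item
#'   above which an item counts as an attrition point (default 0.05).
#' @return List of class `phase_segmentation`: `curiosity_end`,
#'   `attrition_end`, `stable_rate` (mean `pct_respondents` after
#'   `attrition_end`; `NA` when the attrition phase ends at the final
#'   item), `degenerate` flag (no item exceeded the threshold),
#'   `threshold`, and `incremental_prop`.
#' @export
estimate_phases <- function(at, threshold = 0.05) {
  stopifnot(inherits(at, "attrition_table"))
  p <- nrow(at)
  if (p < 3L) config_error("phase estimation needs at least 3 items")
  n0 <- attr(at, "n_starters")
  prop <- at$n_incremental_dropouts / n0
  above <- prop > threshold
  if (!any(above)) {
    return(structure(list(curiosity_end = p, attrition_end = p,
                          stable_rate = NA_real_, degenerate = TRUE,
                          threshold = threshold, incremental_prop = prop),
                     class = "phase_segmentation"))
  }
  first <- which(above)[1L]
  end <- first
  j <- first + 1L
  while (j <= p) {
    if (above[j]) { end <- j; j <- j + 1L }
    else if (j + 1L <= p && above[j + 1L]) { end <- j + 1L; j <- j + 2L }
    else break
  }
  stable <- if (end < p) mean(at$pct_respondents[(end + 1L):p]) else NA_real_
  structure(list(curiosity_end = max(first - 1L, 1L), attrition_end = end,
                 stable_rate = stable, degenerate = FALSE,
                 threshold = threshold, incremental_prop = prop),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("Attrition phase segmentation (heuristic, threshold =",
      x$threshold, "incremental dropout/item)\n")
  if (x$degenerate) {
    cat("  degenerate: no item exceeded the threshold (all curiosity plateau)\n")
  } else {
    cat(sprintf("  curiosity plateau: items 1-%d\n", x$curiosity_end))
    cat(sprintf("  attrition phase:   items %d-%d\n",
                x$curiosity_end + 1L, x$attrition_end))
    if (is.na(x$stable_rate)) {
      cat("  stable phase: none (attrition phase reaches the final item)\n")
    } else {
      cat(sprintf("  stable phase:      items %d+ at %.1f%% participation\n",
                  x$attrition_end + 1L, x$stable_rate))
    }
  }
  invisible(x)
}

#' Write an attrition table to CSV
#' @param at an `attrition_table` or the list returned by a stratified
#'   [summarize_attrition()].
#' @param path output CSV path; stratified input adds a `group` column.
#' @export
write_attrition_csv <- function(at, path) {
  if (inherits(at, "attrition_table")) {
    utils::write.csv(at, path, row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(names(at), function(g) {
      cbind(group = g, as.data.frame(at[[g]]))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
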