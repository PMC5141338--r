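# Figure families: respondent/dropout bar charts (optionally stacked
# with skips or grouped by cohort), survival-type attrition step curves
# with phase annotation, and Kaplan-Meier participation curves. Every
# figure is driven by a coordinate table that can also be exported, so
# no plot contains numbers absent from the exports.

# Okabe-Ito color-blind-safe palette (supports up to 8 groups)
.okabe_ito <- c("#0072B2", "#D55E00", "#009E73", "#CC79A7",
                "#E69F00", "#56B4E9", "#F0E442", "#999999")

.as_group_tables <- function(at) {
  if (inherits(at, "attrition_table")) return(list(pooled = at))
  at
}

#' Coordinate table behind an attrition step curve
#'
#' The step-function coordinates of the percentage of respondents per
#' item (allowed to rise when items are skipped), for one table or a
#' stratified list.
#'
#' @param at an `attrition_table` or stratified list from
#'   [summarize_attrition()].
#' @return Data frame with `group`, `item`, `pct_respondents`.
#' @export
attrition_curve_coords <- function(at) {
  tabs <- .as_group_tables(at)
  do.call(rbind, lapply(names(tabs), function(g) {
    data.frame(group = g, item = tabs[[g]]$item,
               pct_respondents = tabs[[g]]$pct_respondents)
  }))
}

#' Coordinate table behind Kaplan-Meier participation curves
#' @param lr a `logrank_result` (from [logrank_test()]).
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_coords <- function(lr) {
  stopifnot(inherits(lr, "logrank_result"))
  do.call(rbind, lapply(names(lr$curves), function(g) {
    cbind(group = g, lr$curves[[g]])
  }))
}

#' Bar charts of per-item attrition
#'
#' @param at an `attrition_table`, or a stratified list for
#'   `kind = "grouped"`.
#' @param kind `"respondents_pct"` (percent of starters answering each
#'   item), `"dropouts_count"` (incremental dropouts), `"dropouts_pct"`
#'   (cumulative dropout percentage), `"stacked_skips"` (respondent
#'   bars with the skip percentage stacked on top), or `"grouped"`
#'   (per-group bars; percentage scale by default since raw counts
#'   mislead when group sizes differ — a warning is issued for unequal
#'   groups when `counts = TRUE`).
#' @param counts for `kind = "grouped"`, plot raw dropout counts instead
#'   of percentages.
#' @return A ggplot object.
#' @export
plot_attrition_bars <- function(at, kind = c("respondents_pct", "dropouts_count",
                                             "dropouts_pct", "stacked_skips",
                                             "grouped"),
                                counts = FALSE) {
  kind <- match.arg(kind)
  if (kind == "grouped") {
    tabs <- .as_group_tables(at)
    tabs <- tabs[setdiff(names(tabs), "pooled")]
    if (length(tabs) < 2L) config_error("grouped chart needs group-stratified input")
    sizes <- vapply(tabs, function(x) attr(x, "n_starters"), numeric(1))
    if (counts && length(unique(sizes)) > 1L) {
      warning("group sizes are unequal; raw-count comparison is skewed - consider percentages")
    }
    df <- do.call(rbind, lapply(names(tabs), function(g) {
      data.frame(group = g, item = tabs[[g]]$item,
                 value = if (counts) tabs[[g]]$n_incremental_dropouts
                         else tabs[[g]]$pct_dropouts)
    }))
    return(ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$item), y = .data$value,
                                            fill = .data$group)) +
             ggplot2::geom_col(position = "dodge") +
             ggplot2::scale_fill_manual(values = .okabe_ito) +
             ggplot2::labs(x = "Item", fill = "Group",
                           y = if (counts) "Dropouts (n)" else "Dropouts (% of group starters)") +
             ggplot2::theme_minimal())
  }
  if (!inherits(at, "attrition_table")) config_error("'%s' needs a single (pooled) table", kind)
  df <- as.data.frame(at)
  p <- switch(kind,
    respondents_pct = ggplot2::ggplot(df, ggplot2::aes(factor(.data$item), .data$pct_respondents)) +
      ggplot2::geom_col(fill = .okabe_ito[1]) +
      ggplot2::labs(x = "Item", y = "Respondents (% of starters)"),
    dropouts_count = ggplot2::ggplot(df, ggplot2::aes(factor(.data$item), .data$n_incremental_dropouts)) +
      ggplot2::geom_col(fill = .okabe_ito[2]) +
      ggplot2::labs(x = "Item", y = "Dropouts (n)"),
    dropouts_pct = ggplot2::ggplot(df, ggplot2::aes(factor(.data$item), .data$pct_dropouts)) +
      ggplot2::geom_col(fill = .okabe_ito[2]) +
      ggplot2::labs(x = "Item", y = "Cumulative dropouts (% of starters)"),
    stacked_skips = {
      long <- rbind(
        data.frame(item = df$item, part = "answered", value = df$pct_respondents),
        data.frame(item = df$item, part = "skipped", value = df$pct_skips))
      long$part <- factor(long$part, levels = c("skipped", "answered"))
      ggplot2::ggplot(long, ggplot2::aes(factor(.data$item), .data$value,
                                         fill = .data$part)) +
        ggplot2::geom_col(position = "stack") +
        ggplot2::scale_fill_manual(values = c(answered = .okabe_ito[1],
                                              skipped = .okabe_ito[5])) +
        ggplot2::labs(x = "Item", y = "% of starters", fill = NULL)
    })
  p + ggplot2::theme_minimal()
}

#' Survival-type attrition step curve
#'
#' Step function of the respondent percentage by item. Unlike a true
#' survival curve it may rise where many subjects skipped an item.
#' Phase boundaries from [estimate_phases()] can be annotated as
#' vertical lines.
#'
#' @param at an `attrition_table` or stratified list (one curve per
#'   group).
#' @param phases optional `phase_segmentation` to annotate.
#' @return A ggplot object.
#' @export
plot_attrition_curve <- function(at, phases = NULL) {
  df <- attrition_curve_coords(at)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$item, .data$pct_respondents,
                                        color = .data$group)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8) +
    ggplot2::scale_color_manual(values = .okabe_ito) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Item", y = "Respondents (% of starters)", color = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(df$group)) == 1L) {
    p <- p + ggplot2::guides(color = "none")
  }
  if (!is.null(phases) && !phases$degenerate) {
    p <- p + ggplot2::geom_vline(xintercept = c(phases$curiosity_end + 0.5,
                                                phases$attrition_end + 0.5),
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' Kaplan-Meier participation curves by group
#' @param lr a `logrank_result`.
#' @return A ggplot object.
#' @export
plot_km_curves <- function(lr) {
  df <- km_coords(lr)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, color = .data$group)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8) +
    ggplot2::scale_color_manual(values = .okabe_ito) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Item (dropout time)", y = "Still participating",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Render a plot to disk with its coordinate table
#'
#' Writes the figure (`.png`, `.svg` or `.pdf`, inferred from the
#' extension) and, when `coords` is supplied, the underlying coordinate
#' table as a CSV next to it.
#'
#' @param plot a ggplot object.
#' @param path output image path.
#' @param coords optional data frame written to `<path>.csv`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, path, coords = NULL, width = 7, height = 4.5) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg", "pdf")) config_error("unsupported format '%s'", ext)
  dev <- if (ext == "svg") grDevices::svg else NULL
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150,
                  device = dev)
  if (!is.null(coords)) {
    utils::write.csv(coords, paste0(tools::file_path_sans_ext(path), "_coords.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}
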