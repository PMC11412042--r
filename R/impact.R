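#' Weed-induced reductions versus the weed-free control
#'
#' For every (stage, sowing, density, weed_level > 0) treatment cell,
#' compares the mean response against the mean of that cell's own
#' weed-level-0 control and reports the relative reduction
#' (1 - mean / control_mean) and the absolute reduction (kg/ha).
#'
#' @param plot_table data.frame as returned by [simulate_plot_trials()].
#' @param response "wheat_dry_weight" or "grain_yield".
#' @return object of class `reduction_table`: data.frame with stage,
#'   sowing, density, weed_level, n, mean_response, control_mean,
#'   relative_reduction, absolute_reduction.
#' @export
reductions_vs_control <- function(plot_table,
                                  response = c("wheat_dry_weight",
                                               "grain_yield")) {
  response <- match.arg(response)
  req <- c("stage", "sowing", "density", "weed_level", response)
  if (!all(req %in% names(plot_table))) {
    stop("plot table lacks required columns")
  }
  cells <- unique(plot_table[c("stage", "sowing", "density")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- plot_table$stage == cells$stage[r] &
      plot_table$sowing == cells$sowing[r] &
      plot_table$density == cells$density[r]
    sub <- plot_table[sel, ]
    ctrl <- sub[sub$weed_level == 0, response]
    if (length(ctrl) == 0) {
      stop(sprintf("missing weed-free control for cell (%s, %s, %s)",
                   cells$stage[r], cells$sowing[r], cells$density[r]))
    }
    cm <- mean(ctrl)
    for (lv in sort(unique(sub$weed_level[sub$weed_level > 0]))) {
      v <- sub[sub$weed_level == lv, response]
      out[[length(out) + 1L]] <- data.frame(
        stage = cells$stage[r], sowing = cells$sowing[r],
        density = cells$density[r], weed_level = lv, n = length(v),
        mean_response = mean(v), control_mean = cm,
        relative_reduction = 1 - mean(v) / cm,
        absolute_reduction = cm - mean(v), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no weedy treatment rows in the plot table")
  res <- do.call(rbind, out)
  attr(res, "response") <- response
  class(res) <- c("reduction_table", class(res))
  res
}

#' Maximum reduction and its treatment
#'
#' @param reduction_table a `reduction_table`.
#' @param mode "relative" (fraction) or "absolute" (kg/ha).
#' @return list with `value`, and `treatment` (the row's stage, sowing,
#'   density, weed_level). Exact ties are broken toward the first key in
#'   sorted (stage, sowing, density, weed_level) order.
#' @export
max_reduction <- function(reduction_table, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (nrow(reduction_table) == 0) stop("empty reduction table")
  col <- if (mode == "relative") "relative_reduction" else "absolute_reduction"
  v <- reduction_table[[col]]
  best <- which(v == max(v))
  if (length(best) > 1) {
    key <- reduction_table[best, c("stage", "sowing", "density", "weed_level")]
    best <- best[order(key$stage, key$sowing, key$density, key$weed_level)]
  }
  row <- reduction_table[best[1], ]
  list(value = row[[col]],
       treatment = row[c("stage", "sowing", "density", "weed_level")])
}

#' Factor-level contrasts of mean reduction
#'
#' Mean relative reduction per level of each treatment factor and the
#' contrast signs. Under the default generator the expected orderings are
#' broadcast > drill, high > low density and wintering > jointing.
#'
#' @param reduction_table a `reduction_table`.
#' @return data.frame with factor, level_hi, level_lo, mean_hi, mean_lo,
#'   contrast (mean_hi - mean_lo); a factor with a missing level is
#'   reported with `NA` contrast.
#' @export
factor_contrasts <- function(reduction_table) {
  spec <- list(sowing = c("B", "D"), density = c("H", "L"),
               stage = c("W", "J"))
  out <- list()
  for (f in names(spec)) {
    lv <- spec[[f]]
    hi <- reduction_table$relative_reduction[reduction_table[[f]] == lv[1]]
    lo <- reduction_table$relative_reduction[reduction_table[[f]] == lv[2]]
    out[[f]] <- data.frame(
      factor = f, level_hi = lv[1], level_lo = lv[2],
      mean_hi = if (length(hi)) mean(hi) else NA_real_,
      mean_lo = if (length(lo)) mean(lo) else NA_real_,
      contrast = if (length(hi) && length(lo)) mean(hi) - mean(lo)
                 else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Bar chart of reductions, faceted like a field-trial report
#'
#' Renders mean relative reductions per (stage, sowing, density) cell and
#' weed level as grouped bars to a PNG.
#'
#' @param reduction_table a `reduction_table`.
#' @param png_path output path.
#' @export
plot_reductions <- function(reduction_table, png_path) {
  rt <- reduction_table
  rt$cell <- paste(rt$stage, rt$sowing, rt$density, sep = "/")
  cells <- sort(unique(rt$cell))
  levels <- sort(unique(rt$weed_level))
  m <- matrix(0, length(levels), length(cells),
              dimnames = list(levels, cells))
  for (r in seq_len(nrow(rt))) {
    m[as.character(rt$weed_level[r]), rt$cell[r]] <- rt$relative_reduction[r]
  }
  grDevices::png(png_path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::barplot(m * 100, beside = TRUE, las = 2,
                    ylab = "reduction vs control (%)",
                    legend.text = paste("level", levels),
                    main = attr(rt, "response"))
  invisible(png_path)
}
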