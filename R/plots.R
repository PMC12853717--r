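#' Plot metric curves over the below-LLOQ proportion
#'
#' Draws, for one metric, one curve per method of the metric versus the
#' below-LLOQ proportion, faceted by setting (rows) and sample size
#' (columns), one figure per model. Coverage panels are clipped to `[0, 1]`
#' with a dashed reference line at the nominal 0.95. Facets without data
#' are annotated "no data". Files are named `model<id>_<metric>.<ext>`.
#'
#' @param metrics Metrics table from [summarize_metrics()] (nonempty).
#' @param metric One of `"bias"`, `"coverage"`, `"mse"`.
#' @param out_dir Output directory (created if missing).
#' @param ext Image extension understood by [ggplot2::ggsave()].
#' @param width,height Figure size in inches.
#'
#' @return Invisibly, the character vector of files written.
#' @export
plot_metric_curves <- function(metrics, metric = c("bias", "coverage", "mse"),
                               out_dir = ".", ext = "png",
                               width = 9, height = 6) {
  metric <- match.arg(metric)
  if (nrow(metrics) == 0L) stop("`metrics` is empty")
  sub <- metrics[metrics$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for metric '", metric, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character(0)
  for (mid in sort(unique(sub$model_id))) {
    d <- sub[sub$model_id == mid, , drop = FALSE]
    d$n <- factor(d$n, levels = sort(unique(d$n)),
                  labels = paste0("n = ", sort(unique(d$n))))
    p <- ggplot2::ggplot(
      d, ggplot2::aes(x = lloq_proportion, y = value, colour = method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_grid(setting ~ n) +
      ggplot2::labs(x = "proportion below LLOQ", y = metric,
                    colour = "method",
                    title = sprintf("Model %d: %s", mid, metric)) +
      ggplot2::theme_bw()
    if (metric == "coverage") {
      p <- p +
        ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
        ggplot2::coord_cartesian(ylim = c(0, 1))
    }
    empty <- empty_facets(d)
    if (nrow(empty)) {
      p <- p + ggplot2::geom_text(
        data = empty,
        ggplot2::aes(x = x, y = y, label = label),
        inherit.aes = FALSE, size = 3)
    }
    file <- file.path(out_dir, sprintf("model%d_%s.%s", mid, metric, ext))
    ggplot2::ggsave(file, p, width = width, height = height)
    files <- c(files, file)
  }
  invisible(files)
}

# setting x n combinations present in the facet grid but with no rows
empty_facets <- function(d) {
  grid <- expand.grid(setting = unique(d$setting), n = unique(d$n),
                      stringsAsFactors = FALSE)
  have <- unique(d[c("setting", "n")])
  miss <- grid[!paste(grid$setting, grid$n) %in% paste(have$setting, have$n),
               , drop = FALSE]
  if (nrow(miss) == 0L) return(miss)
  miss$x <- mean(range(d$lloq_proportion))
  miss$y <- mean(range(d$value, finite = TRUE))
  miss$label <- "no data"
  miss
}
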