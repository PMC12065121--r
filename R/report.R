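# Figures and machine-readable report bundles for a completed analysis.
# Base graphics; PNG when a bitmap device is available, PDF otherwise.

.open_device <- function(path_base, width = 7, height = 5) {
  png_path <- paste0(path_base, ".png")
  ok <- tryCatch({
    grDevices::png(png_path, width = width * 110, height = height * 110,
                   res = 110, type = "cairo")
    TRUE
  }, error = function(e) FALSE)
  if (ok) return(png_path)
  pdf_path <- paste0(path_base, ".pdf")
  grDevices::pdf(pdf_path, width = width, height = height)
  pdf_path
}

#' Accuracy-vs-perturbation scatter with fitted line
#'
#' @param sweep A `cf_sweep`.
#' @param path_base Output path without extension; `NULL` plots to the
#'   current device.
#' @return The figure path (invisibly), or `NULL` when plotting directly.
#' @export
plot_accuracy_sweep <- function(sweep, path_base = NULL) {
  stopifnot(inherits(sweep, "cf_sweep"))
  path <- if (!is.null(path_base)) .open_device(path_base) else NULL
  on.exit(if (!is.null(path)) grDevices::dev.off(), add = TRUE)
  runs <- sweep$runs
  graphics::plot(runs$level, runs$accuracy, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue4", 0.5),
                 xlab = "Perturbation level", ylab = "Validation accuracy",
                 main = "Clade prediction accuracy under label perturbation")
  if (!is.null(sweep$regression)) {
    graphics::abline(a = sweep$regression$intercept,
                     b = sweep$regression$slope, col = "firebrick", lwd = 2)
    graphics::legend("topright", bty = "n", legend = sprintf(
      "OLS: slope = %.3f, R2 = %.3f", sweep$regression$slope,
      sweep$regression$r_squared))
  } else {
    warning("single perturbation level: no regression line drawn")
  }
  invisible(path)
}

#' Top-importance bar chart at one perturbation level
#'
#' @inheritParams plot_accuracy_sweep
#' @param level Perturbation level present in the sweep.
#' @param top_n Number of columns shown (default 10).
#' @export
plot_importances <- function(sweep, level, top_n = 10L, path_base = NULL) {
  imp <- aggregate_importances(sweep, level, top_n)
  path <- if (!is.null(path_base)) .open_device(path_base, height = 5) else NULL
  on.exit(if (!is.null(path)) grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(4, 12, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::barplot(rev(imp$mean_importance), names.arg = rev(imp$column),
                    horiz = TRUE, las = 1, col = "darkseagreen4",
                    xlab = "Mean impurity importance",
                    main = sprintf("Top metadata at perturbation %.0f%%",
                                   100 * level),
                    cex.names = 0.7)
  invisible(path)
}

#' Render a full report bundle
#'
#' Writes the accuracy-vs-perturbation figure (with OLS line and R2
#' annotation), top-importance bar charts at the requested levels, the runs
#' table, importance tables, the regression summary, a
#' transformation-classification summary (explicit zero counts when no
#' records exist) and a clade-comparison summary, each with a
#' machine-readable JSON next to every figure.
#'
#' @param sweep A `cf_sweep` (required).
#' @param records Optional transformation records
#'   (from [classify_transformations()]).
#' @param comparison Optional result of [compare_clade_sets()].
#' @param out_dir Output directory (created if needed).
#' @param importance_levels Levels for importance charts (only those present
#'   in the sweep are used).
#' @param top_n Columns per importance chart.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(sweep, records = NULL, comparison = NULL,
                          out_dir, importance_levels = c(0, 0.5, 1),
                          top_n = 10L) {
  stopifnot(inherits(sweep, "cf_sweep"))
  if (!nrow(sweep$runs)) stop("empty sweep: nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- function(...) file.path(out_dir, paste0(...))

  utils::write.csv(sweep$runs, p("runs.csv"), row.names = FALSE)
  files <- c(files, p("runs.csv"))

  fig <- plot_accuracy_sweep(sweep, file.path(out_dir, "accuracy_sweep"))
  jsonlite::write_json(
    list(regression = sweep$regression,
         levels = sweep$levels, replicates = sweep$replicates,
         base_seed = sweep$base_seed,
         hyperparameters = sweep$hyperparameters),
    p("accuracy_sweep.json"), auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, fig, p("accuracy_sweep.json"))

  for (lv in importance_levels) {
    if (!any(abs(sweep$runs$level - lv) < 1e-12)) next
    imp <- aggregate_importances(sweep, lv, top_n)
    base <- sprintf("importances_p%03.0f", 100 * lv)
    utils::write.csv(imp, p(base, ".csv"), row.names = FALSE)
    fig <- plot_importances(sweep, lv, top_n, file.path(out_dir, base))
    jsonlite::write_json(imp, p(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, p(base, ".csv"), fig, p(base, ".json"))
  }

  cls <- c("unique", "private", "nonprivate")
  counts <- if (is.null(records) || !nrow(records)) {
    setNames(as.list(rep(0L, length(cls) + 2L)),
             c(cls, "unclassified", "ambiguous"))
  } else {
    tab <- table(factor(records$classification[!records$ambiguous &
                                                 !is.na(records$classification)],
                        levels = cls))
    c(as.list(tab),
      list(unclassified = sum(!records$ambiguous &
                                is.na(records$classification)),
           ambiguous = sum(records$ambiguous)))
  }
  jsonlite::write_json(counts, p("transformations.json"), auto_unbox = TRUE)
  files <- c(files, p("transformations.json"))
  if (!is.null(records) && nrow(records)) {
    utils::write.csv(records, p("transformations.csv"), row.names = FALSE)
    files <- c(files, p("transformations.csv"))
  }

  if (!is.null(comparison)) {
    jsonlite::write_json(comparison, p("tree_comparison.json"),
                         auto_unbox = TRUE)
    files <- c(files, p("tree_comparison.json"))
  }
  invisible(files)
}

#' Write transformation records as CSV
#'
#' Columns: character, node (branch child), clade_size, from, to, ambiguous,
#' classification.
#'
#' @param records From [classify_transformations()].
#' @param file CSV path.
#' @export
write_transformations <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}
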