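#' Exploratory panel for one channel pair
#'
#' The three complementary views used to inspect a pair before the
#' quantitative battery: a time plot of both channels on their original
#' scale, a scatter plot with the least-squares line and the R squared of
#' the raw and moving-averaged versions, and lagged cross-correlation stem
#' plots (raw and moving-averaged) over ±15 s.
#'
#' @param x,y Gap-free original-scale [parameter_series()] on a shared
#'   grid; `x` is the reference (independent) channel.
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix; derived from the channel names when
#'   `NULL`.
#' @param cfg A [benchmark_config()] (moving-average window, lag range).
#' @return Character vector of written file paths (empty, with a warning,
#'   if the pair cannot be plotted).
#' @export
exploratory_panel <- function(x, y, outdir, prefix = NULL,
                              cfg = benchmark_config()) {
  if (is.null(x) || is.null(y) || !length(x$t) || !length(y$t)) {
    warning("empty pair; no panel written")
    return(character(0))
  }
  ov <- pair_overlap(x, y)
  if (is.null(ov) || length(ov$a$t) < cfg$min_overlap) {
    warning("insufficient overlap; no panel written")
    return(character(0))
  }
  x <- ov$a; y <- ov$b
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prefix))
    prefix <- gsub("[^A-Za-z0-9]+", "_",
                   paste(format(x$name), format(y$name), sep = "_vs_"))
  xm <- moving_average(x, cfg$mvavg_half_window_s)
  ym <- moving_average(y, cfg$mvavg_half_window_s)
  r2_raw <- suppressWarnings(linear_r2(x, y))
  r2_mv <- suppressWarnings(linear_r2(xm, ym))
  paths <- character(0)
  save_plot <- function(p, name) {
    f <- file.path(outdir, paste0(prefix, "_", name, ".png"))
    ggplot2::ggsave(f, p, width = 7, height = 4.5, dpi = 110)
    paths <<- c(paths, f)
  }

  td <- rbind(
    data.frame(t_s = x$t / 1000, value = x$v, channel = format(x$name)),
    data.frame(t_s = y$t / 1000, value = y$v, channel = format(y$name)))
  save_plot(
    ggplot2::ggplot(td, ggplot2::aes(.data$t_s, .data$value,
                                     colour = .data$channel)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time [s]", y = x$name$parameter,
                    title = "Time plot (original scale)") +
      ggplot2::theme_minimal(),
    "time")

  sd_ <- data.frame(x = x$v, y = y$v)
  save_plot(
    ggplot2::ggplot(sd_, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.4) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "red", linewidth = 0.5) +
      ggplot2::labs(x = format(x$name), y = format(y$name),
                    title = sprintf("Scatter: R2 = %.3f (raw), %.3f (mv. avg.)",
                                    r2_raw, r2_mv)) +
      ggplot2::theme_minimal(),
    "scatter")

  for (variant in c("raw", "mvavg")) {
    cc <- if (variant == "raw")
      cross_correlation(x, y, max_lag = cfg$max_lag_s) else
      cross_correlation(xm, ym, max_lag = cfg$max_lag_s)
    cd <- data.frame(lag = cc$lags, r = cc$coefficients)
    save_plot(
      ggplot2::ggplot(cd, ggplot2::aes(.data$lag, .data$r)) +
        ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0),
                              linewidth = 0.6) +
        ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
        ggplot2::labs(x = "lag [s]", y = "r",
                      title = sprintf("Cross-correlation (%s), best lag %+d s",
                                      variant, cc$best_lag)) +
        ggplot2::theme_minimal(),
      paste0("ccf_", variant))
  }
  paths
}

#' Heat table of a benchmark matrix
#'
#' Renders the sorted matrix as a tile plot (diverging palette, high
#' agreement in red for correlation statistics and low distance in green
#' for similarity statistics; missing cells grey) and writes the matching
#' CSV, the single source of truth for the cell values.
#'
#' @param bm A [assemble_matrix()] result.
#' @param outdir Output directory.
#' @param name Base file name (defaults to the statistic).
#' @return Named list with `png` and `csv` paths.
#' @export
matrix_heat <- function(bm, outdir, name = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(name)) name <- bm$statistic
  csv <- file.path(outdir, paste0(name, "_matrix.csv"))
  write_benchmark_matrix(bm, csv)
  m <- bm$values
  df <- data.frame(
    pair = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    participant = factor(rep(colnames(m), each = nrow(m)),
                         levels = colnames(m)),
    value = as.vector(m))
  pal <- if (bm$ascending)
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "royalblue",
                                 na.value = "grey85") else
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = stats::median(m, na.rm = TRUE),
                                  na.value = "grey85")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$participant, .data$pair,
                                        fill = .data$value)) +
    ggplot2::geom_tile() + pal +
    ggplot2::labs(title = paste(toupper(bm$statistic), "benchmark matrix"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  png <- file.path(outdir, paste0(name, "_matrix.png"))
  ggplot2::ggsave(png, p, width = 8,
                  height = max(3, 0.18 * nrow(m) + 1.5), dpi = 110,
                  limitsize = FALSE)
  list(png = png, csv = csv)
}
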