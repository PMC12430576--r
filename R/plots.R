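#' Per-chromosome scan figure
#'
#' Three stacked panels per genome -- SNP-index of each bulk and
#' delta(SNP-index) -- with per-site points, the window-mean line and the
#' 95%/99% confidence envelope on the delta panel. Index panels are pinned to
#' `[0, 1]` and the delta panel to `[-1, 1]`. Rendering is best-effort: an
#' empty chromosome yields an empty panel, and file-writing failures are
#' logged, never raised.
#'
#' @param track a filtered [snp_index_track()].
#' @param windows thresholded windows from [attach_thresholds()].
#' @param out_dir directory to write `scan_tracks.png` into, or `NULL` to only
#'   return the plot objects.
#' @return (invisibly) list with the three panel ggplots, the combined
#'   patchwork and the written file path (or `NA`).
#' @export
plot_tracks <- function(track, windows, out_dir = NULL) {
  pass <- track[track$filter_status == "pass", ]
  w <- windows[!windows$missing, ]
  mid <- (windows$start + windows$end) / 2

  panel <- function(site_y, win_y, ylab, ylim, envelope = FALSE) {
    g <- ggplot2::ggplot() +
      ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                          space = "free_x") +
      ggplot2::coord_cartesian(ylim = ylim) +
      ggplot2::labs(x = "position (bp)", y = ylab) +
      ggplot2::theme_bw()
    if (nrow(pass)) {
      g <- g + ggplot2::geom_point(
        data = data.frame(chrom = pass$chrom, pos = pass$pos, y = pass[[site_y]]),
        ggplot2::aes(x = pos, y = y),
        size = 0.4, alpha = 0.4, colour = "grey30")
    }
    if (nrow(w)) {
      wd <- data.frame(chrom = w$chrom, mid = (w$start + w$end) / 2, y = w[[win_y]])
      g <- g + ggplot2::geom_line(data = wd,
                                  ggplot2::aes(x = mid, y = y),
                                  colour = "red", linewidth = 0.5)
      if (envelope) {
        for (cc in list(c("ci99_high", "orange"), c("ci95_high", "green4"),
                        c("ci99_low", "orange"), c("ci95_low", "green4"))) {
          if (!is.null(w[[cc[1]]])) {
            ed <- data.frame(chrom = w$chrom, mid = wd$mid, y = w[[cc[1]]])
            g <- g + ggplot2::geom_line(data = ed,
                                        ggplot2::aes(x = mid, y = y),
                                        colour = cc[2], linetype = "dashed",
                                        linewidth = 0.4)
          }
        }
      }
    }
    g
  }

  g1 <- panel("index_hc1", "mean_index_hc1", "SNP-index (HC1)", c(0, 1))
  g2 <- panel("index_hc2", "mean_index_hc2", "SNP-index (HC2)", c(0, 1))
  g3 <- panel("delta", "mean_delta", expression(Delta * "(SNP-index)"),
              c(-1, 1), envelope = TRUE)
  combined <- patchwork::wrap_plots(g1, g2, g3, ncol = 1)

  file <- NA_character_
  if (!is.null(out_dir)) {
    file <- file.path(out_dir, "scan_tracks.png")
    ok <- tryCatch({
      ggplot2::ggsave(file, combined, width = 3 + 2.5 * length(unique(track$chrom)),
                      height = 8, dpi = 120)
      TRUE
    }, error = function(e) {
      message("plot not written: ", conditionMessage(e))
      FALSE
    })
    if (!ok) file <- NA_character_
  }
  invisible(list(index_hc1 = g1, index_hc2 = g2, delta = g3,
                 combined = combined, file = file))
}
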