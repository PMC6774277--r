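base_fill_colors <- c(A = "#4daf4a", C = "#377eb8", G = "#555555",
                      T = "#e41a1c", N = "#bbbbbb")

#' Scene description for a signature plot
#'
#' Computes the drawable elements of a per-position signature plot without
#' rendering them, so that plot content can be inspected and tested exactly:
#' stacked per-base composition bars (strand-summed counts normalized per
#' position), mismatch markers, arrest markers, and highlight arrows at every
#' position whose mismatch rate exceeds the threshold.
#'
#' @param profile An `rt_profile` data.frame.
#' @param ref_seg Reference name to plot.
#' @param from,to Leftmost and rightmost positions (inclusive); the window
#'   may span at most 1000 bases.
#' @param threshold Highlight threshold on the mismatch rate (default 0.10).
#' @param highlight_on Highlight positions whose `"mismatch"` (default) or
#'   `"arrest"` rate exceeds the threshold.
#' @return A list of data.frames: `bars` (`pos`, `base`, `fraction`),
#'   `rates` (`pos`, `refbase`, `mismatch`, `arrest`), `arrows` (`pos`).
#' @export
signature_scene <- function(profile, ref_seg, from, to, threshold = 0.10,
                            highlight_on = c("mismatch", "arrest")) {
  highlight_on <- match.arg(highlight_on)
  from <- as.integer(from); to <- as.integer(to)
  if (to < from) stop("rightmost position must be >= leftmost position")
  if (to - from + 1L > 1000L) {
    stop("requested window spans ", to - from + 1L,
         " bases; at most 1000 bases can be plotted")
  }
  rows <- as.data.frame(profile)
  rows <- rows[rows$ref_seg == ref_seg & rows$pos >= from & rows$pos <= to, ,
               drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no profile rows for '", ref_seg, "' in window [", from, ", ", to, "]")
  }
  rows <- rows[order(rows$pos), , drop = FALSE]

  comp <- data.frame(
    pos = rep(rows$pos, times = 5L),
    base = rep(c("A", "C", "G", "T", "N"), each = nrow(rows)),
    count = c(rows$A + rows$a, rows$C + rows$c, rows$G + rows$g,
              rows$T + rows$t, rows$N + rows$n),
    stringsAsFactors = FALSE)
  comp$fraction <- comp$count / rows$cov[match(comp$pos, rows$pos)]
  comp <- comp[comp$fraction > 0, , drop = FALSE]
  rownames(comp) <- NULL

  rate_of <- if (highlight_on == "mismatch") rows$mismatch else rows$arrest
  list(bars = comp,
       rates = data.frame(pos = rows$pos, refbase = rows$refbase,
                          mismatch = rows$mismatch, arrest = rows$arrest,
                          stringsAsFactors = FALSE),
       arrows = data.frame(pos = rows$pos[rate_of > threshold]))
}

#' Render a per-position signature plot
#'
#' Draws the classic RT-signature view of a sequence window: stacked colored
#' bars give the per-position base composition of the aligned reads, black
#' crosses mark the mismatch rate, red horizontal dashes mark the arrest
#' rate (shared `[0,1]` axis), and yellow arrows highlight positions whose
#' mismatch rate exceeds the highlight threshold (10% by default). The x
#' axis is labelled with the reference bases.
#'
#' @inheritParams signature_scene
#' @param out Optional output file; format chosen by extension (`.svg`,
#'   `.png` or `.pdf`).
#' @param width,height Device size in inches.
#' @param font_size Base font size in points.
#' @param marker_size Size of the mismatch/arrest markers.
#' @return The ggplot object, invisibly; when `out` is given the plot is
#'   also written to file.
#' @export
render_signature <- function(profile, ref_seg, from, to, out = NULL,
                             width = 10, height = 4, font_size = 11,
                             marker_size = 2.5, threshold = 0.10,
                             highlight_on = c("mismatch", "arrest")) {
  scene <- signature_scene(profile, ref_seg, from, to, threshold,
                           highlight_on)
  rates <- scene$rates
  gg <- ggplot2::ggplot() +
    ggplot2::geom_col(
      data = scene$bars,
      ggplot2::aes(x = pos, y = fraction, fill = base),
      width = 0.85) +
    ggplot2::scale_fill_manual(values = base_fill_colors, name = "read base") +
    ggplot2::geom_point(
      data = rates,
      ggplot2::aes(x = pos, y = mismatch),
      shape = 4, colour = "black", size = marker_size, stroke = 1.1) +
    ggplot2::geom_segment(
      data = rates,
      ggplot2::aes(x = pos - 0.45, xend = pos + 0.45,
                   y = arrest, yend = arrest),
      colour = "red", linewidth = 0.9) +
    ggplot2::scale_y_continuous(limits = c(0, 1.12),
                                breaks = seq(0, 1, 0.25),
                                expand = c(0, 0)) +
    ggplot2::scale_x_continuous(breaks = rates$pos, labels = rates$refbase,
                                expand = c(0.01, 0.01)) +
    ggplot2::labs(x = ref_seg, y = "rate / base fraction") +
    ggplot2::theme_classic(base_size = font_size) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (nrow(scene$arrows) > 0L) {
    gg <- gg + ggplot2::geom_segment(
      data = scene$arrows,
      ggplot2::aes(x = pos, xend = pos, y = 1.11, yend = 1.03),
      colour = "gold2",
      linewidth = 1.1,
      arrow = grid::arrow(length = grid::unit(0.08, "inches"),
                          type = "closed"))
  }
  if (!is.null(out)) {
    ext <- tolower(tools::file_ext(out))
    switch(ext,
           svg = grDevices::svg(out, width = width, height = height),
           png = grDevices::png(out, width = width, height = height,
                                units = "in", res = 150),
           pdf = grDevices::pdf(out, width = width, height = height),
           stop("unsupported image format '.", ext,
                "'; use .svg, .png or .pdf"))
    print(gg)
    grDevices::dev.off()
  }
  invisible(gg)
}
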