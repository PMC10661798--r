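# Plot data and renderings. Numeric plot tables (bins, histograms) are
# the primary artifacts; rendered images are derived views, so tests
# and acceptance run on the tables only.

#' Rose (circular bar) plot of an angle sample
#'
#' @param sample an [angle_sample].
#' @param n_bins number of bins (default 24).
#' @param main plot title.
#' @return invisibly, the bin table from [bin_angles()].
#' @export
rose_plot <- function(sample, n_bins = 24, main = NULL) {
  s <- as_angle_sample(sample)
  bins <- bin_angles(s, n_bins)
  rmax <- max(bins$count, 1)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = main %||% s$label %||% "")
  mult <- 360 / s$period
  for (k in seq_len(nrow(bins))) {
    if (bins$count[k] == 0) next
    r <- sqrt(bins$count[k] / rmax)   # equal-area radius scaling
    th <- deg2rad(seq(bins$bin_start[k], bins$bin_end[k],
                      length.out = 16) * mult)
    graphics::polygon(c(0, r * cos(th)), c(0, r * sin(th)),
                      col = "grey40", border = "white")
    if (s$period == 180) {            # axial data: mirror the sector
      graphics::polygon(c(0, -r * cos(th)), c(0, -r * sin(th)),
                        col = "grey70", border = "white")
    }
  }
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey60")
  invisible(bins)
}

#' Histogram table of translational distances
#'
#' @param td numeric vector of TD values.
#' @param breaks passed to [graphics::hist()] (no plot is drawn).
#' @return data frame `bin_start, bin_end, count`.
#' @export
td_histogram <- function(td, breaks = "Sturges") {
  h <- graphics::hist(td[!is.na(td)], breaks = breaks, plot = FALSE)
  data.frame(bin_start = h$breaks[-length(h$breaks)],
             bin_end = h$breaks[-1], count = h$counts)
}
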