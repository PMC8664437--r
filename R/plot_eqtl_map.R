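# Trans-eQTL map: peak-marker genomic position against the position of each
# transcript's cognate gene. Cis effects land on the diagonal, trans effects
# off it; strong trans hotspots appear as vertical bands.

#' Plot a trans-eQTL map
#'
#' Scatter of the genome-wide position of each trait's peak marker (x axis)
#' against the position of the trait's cognate gene (y axis), restricted to
#' peaks whose LOD exceeds `lod_threshold`. Traits without an annotation
#' entry (no good match to a known gene) are not shown. Both axes concatenate
#' chromosomes in map order with cumulative offsets; chromosome boundaries
#' are drawn. Positions are in Mb when the annotation/map provide Mb,
#' otherwise cM.
#'
#' @param peaks Peak data.frame (`trait_id`, `marker_id`, `chromosome`,
#'   `position_cM`, `lod`) or a `lod_result` in peaks mode.
#' @param annotation data.frame with columns `trait`, `chr`, `pos` giving the
#'   cognate-gene position of each annotated trait, on the same coordinate
#'   scale as the marker positions.
#' @param lod_threshold Only peaks with LOD strictly above this are plotted.
#'   Default 5.
#' @param file Output image path (`.png`); if `NULL`, the ggplot object is
#'   returned without writing.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The ggplot object, invisibly; if `file` is given the plot is also
#'   written there.
#' @export
plot_eqtl_map <- function(peaks, annotation, lod_threshold = 5, file = NULL,
                          width = 6, height = 6, dpi = 150) {
  if (inherits(peaks, "lod_result")) {
    if (is.null(peaks$peaks)) stop("lod_result is in full mode; need peaks")
    peaks <- peaks$peaks
  }
  stopifnot(all(c("trait_id", "chromosome", "position_cM", "lod") %in% names(peaks)),
            all(c("trait", "chr", "pos") %in% names(annotation)))

  sel <- peaks[peaks$lod > lod_threshold, , drop = FALSE]
  df <- merge(sel, annotation, by.x = "trait_id", by.y = "trait")
  if (nrow(df) == 0L)
    warning("no annotated peaks above LOD ", lod_threshold,
            "; writing an empty plot")

  chrs <- unique(c(peaks$chromosome, annotation$chr))
  # numeric chromosome labels first in numeric order, then the rest (X, Y...)
  num <- suppressWarnings(as.numeric(chrs))
  chrs <- c(chrs[!is.na(num)][order(num[!is.na(num)])], sort(chrs[is.na(num)]))
  chr_len <- vapply(chrs, function(ch) {
    max(c(peaks$position_cM[peaks$chromosome == ch],
          annotation$pos[annotation$chr == ch], 0), na.rm = TRUE)
  }, numeric(1))
  offset <- stats::setNames(cumsum(c(0, utils::head(chr_len, -1L))), chrs)
  bounds <- cumsum(chr_len)

  if (nrow(df)) {
    df$x <- offset[df$chromosome] + df$position_cM
    df$y <- offset[as.character(df$chr)] + df$pos
  } else {
    df$x <- df$y <- numeric(0)
  }

  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_vline(xintercept = bounds, colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = bounds, colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, colour = "#2c5f8a") +
    ggplot2::scale_x_continuous(breaks = offset + chr_len / 2, labels = chrs,
                                expand = c(0.01, 0)) +
    ggplot2::scale_y_continuous(breaks = offset + chr_len / 2, labels = chrs,
                                expand = c(0.01, 0)) +
    ggplot2::labs(x = "peak marker position (chromosome)",
                  y = "cognate gene position (chromosome)",
                  title = paste0("eQTL map (LOD > ", lod_threshold, ", ",
                                 nrow(df), " transcripts)")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())

  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi,
                    device = grDevices::png, type = "cairo")
  }
  invisible(p)
}
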