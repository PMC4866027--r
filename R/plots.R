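#' Plot a probe track with its segments and calls
#'
#' Per-chromosome scatter of probe log2 ratios with segment means overlaid
#' and the classification thresholds drawn as dashed lines -- the standard
#' view for inspecting copy-number evidence probe by probe.
#'
#' @param track Probe tibble for one sample.
#' @param segments Optional segment tibble from [segment_track()].
#' @param thresholds An [sv_thresholds()] for the dashed guide lines.
#' @return A ggplot object.
#' @export
plot_track <- function(track, segments = NULL, thresholds = sv_thresholds()) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = position / 1e6, y = log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5, colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(thresholds$upper, thresholds$lower),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(log[2] ~ ratio))
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = start_bp / 1e6, xend = end_bp / 1e6,
                   y = mean_log2, yend = mean_log2),
      colour = "dodgerblue3", linewidth = 1
    )
  }
  p
}

#' Coverage view of an insertion locus
#'
#' Read-depth profile around the first insertion call, with the refined
#' left-border-adjacent coordinate marked; an adjacent deletion shows as a
#' depth hole next to the mark.
#'
#' @param object An `insertion_analysis`.
#' @param window Half-width of the plotted window in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot insertion_analysis
#' @export
autoplot.insertion_analysis <- function(object, window = 5000, ...) {
  if (nrow(object$calls) == 0) {
    abort("no insertion call to plot")
  }
  call <- object$calls[1, ]
  aln <- filter(object$host_aln, aligned)
  lo <- max(1, call$lb_adjacent_coordinate - window)
  hi <- call$lb_adjacent_coordinate + window
  cov <- coverage_vector(aln$pos, object$read_length,
                         max(aln$pos) + object$read_length)
  hi <- min(hi, length(cov))
  df <- tibble(position = lo:hi, depth = cov[lo:hi])
  ggplot2::ggplot(df, ggplot2::aes(position, depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_vline(xintercept = call$lb_adjacent_coordinate,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s position (bp)", call$chromosome),
      y = "read depth",
      title = sprintf("T-DNA insertion at %s:%s (%s)", call$chromosome,
                      format(call$lb_adjacent_coordinate, big.mark = ","),
                      call$orientation)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-sample private substitution counts
#'
#' @param counts Tibble from [per_sample_counts()].
#' @return A ggplot bar chart.
#' @export
plot_substitution_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(sample_id, n_private)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "private homozygous substitutions")
}
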