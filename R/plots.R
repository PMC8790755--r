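#' @include reciprocity.R
NULL

#' Histogram of channel-pair distances against the random baseline
#'
#' Faceted histograms (one panel per channel pair) of the top-voxel
#' distances, overlaid with the random occupancy-gated baseline
#' distribution. Requires ggplot2.
#'
#' @param study a [DistanceStudyResult].
#' @param binwidth histogram bin width in Angstrom (default 1).
#' @return a ggplot object.
#' @export
plotDistanceDistributions <- function(study, binwidth = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotDistanceDistributions requires the ggplot2 package")
  rec <- studyRecords(study)
  long <- rbind(
    data.frame(pair = rec$pair, distance = rec$distance,
               which = "attribution"),
    data.frame(pair = rec$pair, distance = rec$baselineDistance,
               which = "random baseline"))
  long <- long[!is.na(long$distance), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, fill = .data$which)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.55, boundary = 0) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "top-voxel pair distance (Å)", y = "complexes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
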