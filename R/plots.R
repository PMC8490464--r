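#' Plot a binned ratio distribution
#'
#' Histogram-style line plot of bin frequencies with reference lines at the
#' no-change ratio 1.00, the gene-dosage ratio 1.50 and the inverse-dosage
#' ratio 0.67.
#'
#' @param x a [RatioDistribution-class] (or a named list of them, overlaid).
#' @param main plot title.
#' @param col line colour(s).
#' @return invisibly, `NULL`; draws on the active device.
#' @export
plotRatioDistribution <- function(x, main = "Ratio distribution",
                                  col = c("grey40", "red", "blue")) {
  dists <- if (is(x, "RatioDistribution")) list(x) else x
  centers <- lapply(dists, function(d)
    (d@breaks[-length(d@breaks)] + d@breaks[-1]) / 2)
  ymax <- max(vapply(dists, function(d) max(d@counts), numeric(1)))
  plot(NULL, xlim = range(unlist(centers)), ylim = c(0, ymax * 1.05),
       xlab = "expression ratio (experimental / control)",
       ylab = if (dists[[1]]@percent) "% of genes" else "genes per bin",
       main = main)
  abline(v = 1.00, col = "red")
  abline(v = 1.50, col = "blue")
  abline(v = 0.67, col = "blue", lty = 2)
  for (i in seq_along(dists))
    lines(centers[[i]], dists[[i]]@counts, col = col[(i - 1) %% length(col) + 1])
  if (!is.null(names(dists)))
    legend("topright", legend = names(dists), lty = 1,
           col = col[seq_along(dists)], bty = "n")
  invisible(NULL)
}

#' Plot a smoothed chromosome fold-change profile
#'
#' Smoothed log2 fold changes against the equidistant gene index, with a
#' zero line and vertical separators between chromosome arms; up-regulated
#' stretches are drawn dark blue, down-regulated light blue.
#'
#' @param profile `data.frame` from [lowessProfile()] or
#'   [chromosomeProfile()].
#' @param main plot title.
#' @return invisibly, `NULL`; draws on the active device.
#' @export
plotChromosomeProfile <- function(profile, main = "Chromosome profile") {
  plot(profile$index, profile$log2fc, pch = ".", col = "grey70",
       xlab = "genes ordered along chromosomes", ylab = "log2 fold change",
       main = main)
  abline(h = 0, col = "red")
  b <- attr(profile, "boundaries")
  if (!is.null(b)) abline(v = b[-length(b)] + 0.5, col = "grey30")
  up <- profile$smoothed >= 0
  points(profile$index[up], profile$smoothed[up], pch = 20, cex = 0.3,
         col = "darkblue")
  points(profile$index[!up], profile$smoothed[!up], pch = 20, cex = 0.3,
         col = "lightblue3")
  invisible(NULL)
}
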