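#' Per-gene log2 fold change between two groups
#'
#' @param means genes x groups matrix of positive group means.
#' @param experimental,control group column names.
#' @return named numeric vector, `log2(experimental / control)` per gene.
#' @export
log2FoldChange <- function(means, experimental, control) {
  e <- means[, experimental]
  c0 <- means[, control]
  if (any(e <= 0) || any(c0 <= 0))
    stop("internal error: non-positive means reached fold-change stage")
  lfc <- log2(e / c0)
  names(lfc) <- rownames(means)
  lfc
}

#' Order genes equidistantly along the chromosomes
#'
#' Sorts genes by arm (fixed order X, 2L, 2R, 3L, 3R, 4), then ordinal
#' position, ties by gene id, and assigns consecutive indices so genes are
#' plotted at equal spacing. Arm boundary indices mark where the vertical
#' separators fall.
#'
#' @param annotation gene annotation (gene_id, arm, position).
#' @return list with `order` (`data.frame`: gene_id, arm, index) and
#'   `boundaries` (named integer vector, last index of each arm present).
#' @export
orderEquidistant <- function(annotation) {
  if (nrow(annotation) == 0) stop("annotation is empty")
  armF <- factor(annotation$arm, levels = .ARMS)
  ord <- order(armF, annotation$position, annotation$gene_id)
  df <- data.frame(gene_id = annotation$gene_id[ord],
                   arm = annotation$arm[ord],
                   index = seq_along(ord), stringsAsFactors = FALSE)
  bounds <- vapply(split(df$index, factor(df$arm, levels = unique(df$arm))),
                   max, numeric(1))
  list(order = df, boundaries = bounds)
}

#' LOWESS-smoothed chromosome fold-change profile
#'
#' Locally weighted linear regression (tricube weights, robustifying
#' iterations) of per-gene log2 fold changes against their equidistant index,
#' smoothed independently within each arm so that no signal bleeds across
#' the arm separators. Arms with fewer than 3 genes are passed through
#' unsmoothed with a warning.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param annotation annotation rows covering the genes in `log2fc`.
#' @param frac LOWESS span as a fraction of the arm's genes (default 0.05).
#' @param iterations robustifying iterations (default 3).
#' @return `data.frame` with gene_id, arm, index, log2fc, smoothed, ordered
#'   along the genome.
#' @export
lowessProfile <- function(log2fc, annotation, frac = 0.05, iterations = 3L) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  ann <- annotation[annotation$gene_id %in% names(log2fc), , drop = FALSE]
  oe <- orderEquidistant(ann)
  df <- oe$order
  df$log2fc <- unname(log2fc[df$gene_id])
  df$smoothed <- NA_real_
  for (a in unique(df$arm)) {
    sel <- df$arm == a
    y <- df$log2fc[sel]
    if (sum(sel) < 3) {
      warning("arm ", a, " has fewer than 3 genes; returned unsmoothed")
      df$smoothed[sel] <- y
    } else {
      fit <- stats::lowess(x = seq_along(y), y = y, f = frac,
                           iter = iterations)
      df$smoothed[sel] <- fit$y
    }
  }
  attr(df, "boundaries") <- oe$boundaries
  df
}

#' Segment a smoothed profile into up/down-regulated regions
#'
#' Maximal runs of the sign of the smoothed value within each arm. Zeros
#' attach to the preceding run; leading zeros attach to the following run;
#' an all-zero arm forms a single region of direction `"none"`.
#'
#' @param profile `data.frame` from [lowessProfile()] (needs arm, index,
#'   smoothed).
#' @return `data.frame` with arm, start, end (indices, inclusive), direction
#'   (`"up"`, `"down"`, `"none"`).
#' @export
segmentRegions <- function(profile) {
  out <- list()
  for (a in unique(profile$arm)) {
    sub <- profile[profile$arm == a, , drop = FALSE]
    s <- sign(sub$smoothed)
    if (all(s == 0)) {
      out[[length(out) + 1L]] <- data.frame(
        arm = a, start = min(sub$index), end = max(sub$index),
        direction = "none", stringsAsFactors = FALSE)
      next
    }
    ## carry the preceding sign across zeros; leading zeros take the
    ## following sign
    for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
    firstNz <- which(s != 0)[1]
    if (firstNz > 1) s[seq_len(firstNz - 1)] <- s[firstNz]
    r <- rle(s)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    out[[length(out) + 1L]] <- data.frame(
      arm = a, start = sub$index[startIdx], end = sub$index[endIdx],
      direction = ifelse(r$values > 0, "up", "down"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Full chromosome profile for one contrast
#'
#' Convenience wrapper: log2 fold change, equidistant ordering and per-arm
#' LOWESS smoothing in one call.
#'
#' @inheritParams log2FoldChange
#' @inheritParams lowessProfile
#' @return `data.frame` as returned by [lowessProfile()].
#' @export
chromosomeProfile <- function(means, experimental, control, annotation,
                              frac = 0.05, iterations = 3L) {
  lfc <- log2FoldChange(means, experimental, control)
  lowessProfile(lfc, annotation, frac = frac, iterations = iterations)
}
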