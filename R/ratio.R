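#' Per-gene experimental/control expression ratios
#'
#' Divides each gene's experimental group mean by its control group mean and
#' tags each gene with a chromosome class relative to the dosage-varied arm:
#' `"X"`, `"varied_arm"`, or `"other_autosome"` (when the varied arm is X
#' itself, autosomal genes are all `"other_autosome"`).
#'
#' @param means genes x groups matrix of group-mean expression (all positive;
#'   non-positive genes must have been filtered upstream).
#' @param experimental,control group (genotype) column names.
#' @param annotation annotation rows for the genes in `means`.
#' @param variedArm the dosage-varied arm of the experimental karyotype.
#' @return `data.frame` with gene_id, ratio, chrom_class.
#' @export
computeRatios <- function(means, experimental, control, annotation,
                          variedArm) {
  if (!experimental %in% colnames(means) || !control %in% colnames(means))
    stop("experimental and control groups must be columns of means")
  if (!variedArm %in% .ARMS) stop("unknown arm: ", variedArm)
  e <- means[, experimental]
  c0 <- means[, control]
  if (any(c0 <= 0) || any(e <= 0))
    stop("internal error: non-positive group means reached ratio stage")
  ann <- annotation[rownames(means), , drop = FALSE]
  cls <- ifelse(ann$arm == variedArm, "varied_arm",
                ifelse(ann$arm == "X", "X", "other_autosome"))
  data.frame(gene_id = rownames(means), ratio = unname(e / c0),
             chrom_class = cls, row.names = rownames(means),
             stringsAsFactors = FALSE)
}

#' Bin a ratio distribution
#'
#' Half-open constant-width bins `[lo + k w, lo + (k+1) w)` over
#' `[lo, hi)`; ratios at or above `hi` are accumulated in an overflow count
#' rather than a bin. With `asPercent = TRUE` frequencies are expressed as
#' percentages of the in-range total (the convention of 0.1-width sex-bias
#' plots).
#'
#' @param ratios numeric vector of positive ratios, or the `data.frame`
#'   returned by [computeRatios()].
#' @param width bin width (default 0.05).
#' @param lo,hi range (default `[0, 3)`).
#' @param asPercent report percentages instead of raw frequencies.
#' @return a [RatioDistribution-class].
#' @export
binRatioDistribution <- function(ratios, width = 0.05, lo = 0, hi = 3,
                                 asPercent = FALSE) {
  if (is.data.frame(ratios)) ratios <- ratios$ratio
  if (length(ratios) == 0) stop("empty ratio set")
  if (width <= 0) stop("width must be positive")
  if (lo >= hi) stop("lo must be below hi")
  nBins <- ceiling((hi - lo) / width - 1e-9)
  breaks <- lo + width * (0:nBins)
  idx <- floor((ratios - lo) / width) + 1L
  inRange <- ratios >= lo & idx <= nBins
  overflow <- sum(ratios >= breaks[nBins + 1L])
  counts <- tabulate(idx[inRange], nbins = nBins)
  n <- sum(counts)
  cnt <- if (asPercent && n > 0) 100 * counts / n else as.numeric(counts)
  new("RatioDistribution", breaks = breaks, counts = cnt,
      overflow = as.numeric(overflow), percent = asPercent, n = as.integer(n))
}

#' Modal peak of a binned ratio distribution
#'
#' Center of the bin with the maximal frequency. Ties are broken toward the
#' bin whose center is nearest the no-change ratio 1.0, then toward the lower
#' bin.
#'
#' @param x a [RatioDistribution-class].
#' @param ... ignored.
#' @return numeric bin center.
#' @rdname modalPeak
#' @export
setMethod("modalPeak", "RatioDistribution", function(x, ...) {
  if (all(x@counts == 0)) stop("all bin frequencies are zero")
  centers <- (x@breaks[-length(x@breaks)] + x@breaks[-1]) / 2
  cand <- which(x@counts == max(x@counts))
  if (length(cand) > 1) {
    d <- abs(centers[cand] - 1)
    cand <- cand[d == min(d)]
    cand <- cand[which.min(centers[cand])]
  }
  centers[cand]
})

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute difference between the two
#' empirical CDFs over the pooled sample values. The p-value is the
#' asymptotic series Q(lambda) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
#' with the standard small-sample correction
#' lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D, ne = na nb/(na+nb), clamped
#' to (0, 1].
#'
#' @param a,b numeric samples (nonempty).
#' @return list with elements `D` and `p.value`.
#' @export
ksTwoSample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  D <- max(abs(Fa - Fb))
  list(D = D, p.value = .ksPvalue(D, length(a), length(b)))
}

.ksPvalue <- function(D, na, nb) {
  if (D <= 0) return(1)
  ne <- na * nb / (na + nb)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}
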