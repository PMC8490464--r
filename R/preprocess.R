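#' Remove low-count genes
#'
#' Keeps genes whose summed raw counts across all samples reach `minTotal`
#' (default 10 reads), preserving gene order.
#'
#' @param ae an [AneuploidyExperiment-class].
#' @param minTotal minimum total read count per gene (>= 0).
#' @return the filtered [AneuploidyExperiment-class].
#' @export
prefilterLowCounts <- function(ae, minTotal = 10L) {
  stopifnot(is(ae, "AneuploidyExperiment"))
  if (minTotal < 0) stop("minTotal must be >= 0")
  keep <- rowSums(assay(ae, "counts")) >= minTotal
  if (!any(keep))
    warning("all genes fall below the count threshold; returning 0 genes")
  ae[keep, ]
}

#' Counts per million
#'
#' Within-sample library-size normalization: each count is divided by the
#' sample's total mapped reads and scaled to one million.
#'
#' @param ae an [AneuploidyExperiment-class].
#' @return numeric matrix of CPM values, genes x samples (columns sum to 1e6).
#' @export
cpmNormalize <- function(ae) {
  cts <- assay(ae, "counts")
  tot <- colSums(cts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(cts)[tot == 0], collapse = ", "))
  sweep(cts, 2, tot, "/") * 1e6
}

#' Average replicate columns into group means
#'
#' @param expr numeric matrix, genes x samples.
#' @param grouping vector mapping each column to a group (e.g. genotype
#'   labels), length `ncol(expr)`.
#' @return numeric matrix, genes x groups (arithmetic means).
#' @export
averageReplicates <- function(expr, grouping) {
  grouping <- as.character(grouping)
  if (length(grouping) != ncol(expr))
    stop("grouping must assign every sample to exactly one group")
  groups <- unique(grouping)
  out <- vapply(groups, function(g)
    rowMeans(expr[, grouping == g, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1) out <- matrix(out, nrow = 1, dimnames =
                                       list(rownames(expr), groups))
  colnames(out) <- groups
  rownames(out) <- rownames(expr)
  out
}

#' Drop genes with non-positive expression values
#'
#' Genes with any value `<= 0` in the supplied matrix (typically group-mean
#' CPM) are removed: such genes would generate ratios of extreme or undefined
#' value downstream.
#'
#' @param expr numeric matrix, genes x columns.
#' @return the matrix restricted to all-positive rows.
#' @export
removeNonpositive <- function(expr) {
  keep <- apply(expr > 0, 1, all)
  if (!any(keep))
    warning("no gene has all-positive expression; returning 0 genes")
  expr[keep, , drop = FALSE]
}

#' Group-mean CPM pipeline for ratio analysis
#'
#' The fixed preprocessing order behind the ratio and profile stages:
#' count prefilter, CPM, temporary log2(CPM + offset) transform, empirical-
#' Bayes batch adjustment when the design spans more than one sequencing
#' batch, back-transform, per-genotype replicate averaging, and removal of
#' genes with any non-positive group mean.
#'
#' @param ae an [AneuploidyExperiment-class].
#' @param minTotal count prefilter threshold (default 10).
#' @param logOffset offset of the temporary log2 transform (default 0.5).
#' @param batchAdjust `"auto"` (adjust when >1 batch), `TRUE` or `FALSE`.
#' @return list with `means` (genes x genotypes matrix of group-mean CPM)
#'   and `annotation` (annotation rows for the retained genes).
#' @export
groupMeansCPM <- function(ae, minTotal = 10L, logOffset = 0.5,
                          batchAdjust = "auto") {
  ae <- prefilterLowCounts(ae, minTotal)
  cpm <- cpmNormalize(ae)
  ss <- sampleSheet(ae)
  nBatch <- length(unique(ss$batch))
  doAdjust <- if (identical(batchAdjust, "auto")) nBatch > 1
              else isTRUE(batchAdjust)
  if (doAdjust && nBatch > 1) {
    lg <- log2(cpm + logOffset)
    grp <- ss$genotype
    bd <- stats::model.matrix(~ 0 + factor(ss$batch))
    gd <- stats::model.matrix(~ factor(grp))[, -1, drop = FALSE]
    if (qr(cbind(bd, gd))$rank < ncol(bd) + ncol(gd)) {
      message("genotype groups are nested within sequencing batches; ",
              "batch adjustment runs without group covariates")
      grp <- NULL
    }
    lg <- combatAdjust(lg, batch = ss$batch, group = grp)
    cpm <- pmax(2^lg - logOffset, 0)
  }
  means <- averageReplicates(cpm, ss$genotype)
  means <- removeNonpositive(means)
  ann <- geneAnnotation(ae)
  list(means = means, annotation = ann[rownames(means), , drop = FALSE])
}
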