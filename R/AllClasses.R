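#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## canonical arm order used everywhere (profiles, annotation validation)
.ARMS <- c("X", "2L", "2R", "3L", "3R", "4")

#' Karyotype of a (possibly aneuploid) fly
#'
#' Copy numbers per chromosome arm, the sex, and whether an MSL2 transgene is
#' present. The diploid baseline is two copies of every autosomal arm; females
#' carry two or three X chromosomes, males one.
#'
#' @slot copies named integer vector, copies per arm (names among X, 2L, 2R,
#'   3L, 3R, 4), each in 1..3.
#' @slot sex `"female"` or `"male"`.
#' @slot msl2 logical, ectopic MSL2 transgene present.
#' @slot label genotype label used in sample sheets.
#' @export
setClass("Karyotype",
  representation(copies = "integer", sex = "character", msl2 = "logical",
                 label = "character"))

setValidity("Karyotype", function(object) {
  msg <- character()
  if (!all(names(object@copies) %in% .ARMS))
    msg <- c(msg, paste0("unknown arm(s): ",
      paste(setdiff(names(object@copies), .ARMS), collapse = ", ")))
  if (!object@sex %in% c("female", "male"))
    msg <- c(msg, "sex must be 'female' or 'male'")
  if (any(object@copies < 1L | object@copies > 3L))
    msg <- c(msg, "arm copy numbers must be in 1..3")
  x <- object@copies["X"]
  if (!is.na(x)) {
    if (object@sex == "male" && x != 1L)
      msg <- c(msg, "male X copy number must be 1")
    if (object@sex == "female" && !x %in% c(2L, 3L))
      msg <- c(msg, "female X copy number must be 2 or 3")
  }
  if (length(msg)) msg else TRUE
})

#' Multiplicative generative effect model for aneuploid expression
#'
#' Per-gene baseline means (CPM scale) and NB dispersions plus the global
#' multiplicative factors of the dosage-effect model: cis gene-dosage (c/2 on
#' the varied arm), trans inverse-dosage (2/c for responsive genes when a
#' varied arm has c copies), female-specific MSL2 trans-repression, sex-bias
#' multipliers, and per-batch shifts.
#'
#' @slot geneIds character, parallel to `baselineMean`/`dispersion`.
#' @slot baselineMean positive numeric, expected CPM per gene.
#' @slot dispersion non-negative numeric; NB variance = mu + alpha mu^2.
#' @slot inverseDosage logical; if `FALSE` the trans inverse-dosage response
#'   is switched off (cis-only model).
#' @slot msl2Factor numeric in (0, 1]; applied to responsive genes in
#'   MSL2-transgene females (males keep 1.0).
#' @slot sexBiasMult numeric >= 1; multiplier for sex-biased genes in the
#'   biased sex.
#' @slot batchLog2Shift named numeric, additive offset on the log2 scale per
#'   batch.
#' @slot batchScale named numeric, multiplicative scale factor per batch.
#' @export
setClass("EffectModel",
  representation(geneIds = "character", baselineMean = "numeric",
                 dispersion = "numeric", inverseDosage = "logical",
                 msl2Factor = "numeric", sexBiasMult = "numeric",
                 batchLog2Shift = "numeric", batchScale = "numeric"))

setValidity("EffectModel", function(object) {
  msg <- character()
  n <- length(object@geneIds)
  if (length(object@baselineMean) != n || length(object@dispersion) != n)
    msg <- c(msg, "baselineMean and dispersion must match geneIds in length")
  if (any(object@baselineMean < 0)) msg <- c(msg, "baselineMean must be >= 0")
  if (any(object@dispersion < 0)) msg <- c(msg, "dispersion must be >= 0")
  if (object@msl2Factor <= 0 || object@msl2Factor > 1)
    msg <- c(msg, "msl2Factor must lie in (0, 1]")
  if (object@sexBiasMult <= 0) msg <- c(msg, "sexBiasMult must be positive")
  if (any(object@batchScale <= 0)) msg <- c(msg, "batchScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Container for aneuploid RNA-seq counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay of
#' non-negative integers, gene annotation (arm, position, truth labels) in
#' `rowData` and the sample sheet (genotype, sex, batch, replicate) in
#' `colData`.
#'
#' @export
setClass("AneuploidyExperiment", contains = "SummarizedExperiment")

setValidity("AneuploidyExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cts <- assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  need <- c("genotype", "sex", "batch", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  needG <- c("arm", "position")
  missG <- setdiff(needG, colnames(rowData(object)))
  if (length(missG))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(missG, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Binned distribution of expression ratios
#'
#' Frequencies of per-gene experimental/control expression ratios in
#' constant-width half-open bins `[lo + k w, lo + (k+1) w)`; ratios at or above
#' the upper range limit are kept in an overflow count, not a bin.
#'
#' @slot breaks increasing numeric bin edges (length = bins + 1).
#' @slot counts non-negative numeric frequencies (raw counts or percentages).
#' @slot overflow number of ratios at or above the last edge.
#' @slot percent logical; `TRUE` if `counts` are percentages of the in-range
#'   total.
#' @slot n total number of ratios binned (in range).
#' @export
setClass("RatioDistribution",
  representation(breaks = "numeric", counts = "numeric", overflow = "numeric",
                 percent = "logical", n = "integer"))

setValidity("RatioDistribution", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@breaks) - 1L)
    msg <- c(msg, "counts must have length(breaks) - 1")
  w <- diff(object@breaks)
  if (any(w <= 0) || diff(range(w)) > 1e-8 * mean(w))
    msg <- c(msg, "breaks must be increasing with constant width")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Coexpression module assignment with eigengenes
#'
#' Gene-to-module labels (the color convention of weighted coexpression
#' analysis; `"grey"` marks unclustered genes) with, once computed, one
#' eigengene value per module and sample and the variance explained by each
#' eigengene.
#'
#' @slot labels named character, gene id -> module label.
#' @slot eigengenes numeric matrix, modules x samples (0 rows until computed).
#' @slot varianceExplained named numeric in `[0, 1]` per module.
#' @export
setClass("ModuleSet",
  representation(labels = "character", eigengenes = "matrix",
                 varianceExplained = "numeric"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by gene id")
  if (nrow(object@eigengenes) > 0) {
    if (!all(rownames(object@eigengenes) %in% setdiff(object@labels, "grey")))
      msg <- c(msg, "eigengene rows must be non-grey module labels")
    bad <- object@varianceExplained < -1e-8 | object@varianceExplained > 1 + 1e-8
    if (any(bad)) msg <- c(msg, "varianceExplained must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
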