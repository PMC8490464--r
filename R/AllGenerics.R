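#' @rdname geneAnnotation
#' @export
setGeneric("geneAnnotation", function(x, ...) standardGeneric("geneAnnotation"))

#' @rdname sampleSheet
#' @export
setGeneric("sampleSheet", function(x, ...) standardGeneric("sampleSheet"))

#' @rdname modalPeak
#' @export
setGeneric("modalPeak", function(x, ...) standardGeneric("modalPeak"))

#' @rdname moduleLabels
#' @export
setGeneric("moduleLabels", function(x, ...) standardGeneric("moduleLabels"))

#' @rdname eigengenes
#' @export
setGeneric("eigengenes", function(x, ...) standardGeneric("eigengenes"))

#' @rdname varianceExplained
#' @export
setGeneric("varianceExplained",
           function(x, ...) standardGeneric("varianceExplained"))

#' Gene annotation of an experiment
#'
#' @param x an [AneuploidyExperiment-class].
#' @param ... ignored.
#' @return `data.frame` with gene_id, arm, position and truth-label columns.
#' @rdname geneAnnotation
#' @export
setMethod("geneAnnotation", "AneuploidyExperiment", function(x, ...) {
  df <- as.data.frame(rowData(x))
  df <- cbind(gene_id = rownames(x), df)
  rownames(df) <- rownames(x)
  df
})

#' Sample sheet of an experiment
#'
#' @param x an [AneuploidyExperiment-class].
#' @param ... ignored.
#' @return `data.frame` with sample_id, genotype, sex, batch, replicate.
#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "AneuploidyExperiment", function(x, ...) {
  df <- as.data.frame(colData(x))
  df <- cbind(sample_id = colnames(x), df)
  rownames(df) <- colnames(x)
  df
})

#' Module labels of a ModuleSet
#'
#' @param x a [ModuleSet-class].
#' @param ... ignored.
#' @return named character vector, gene id -> module label.
#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(x, ...) x@labels)

#' Eigengene matrix of a ModuleSet
#'
#' @param x a [ModuleSet-class].
#' @param ... ignored.
#' @return numeric matrix, modules x samples.
#' @rdname eigengenes
#' @export
setMethod("eigengenes", "ModuleSet", function(x, ...) x@eigengenes)

#' Variance explained by each module eigengene
#'
#' @param x a [ModuleSet-class].
#' @param ... ignored.
#' @return named numeric vector in `[0, 1]`.
#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "ModuleSet", function(x, ...)
  x@varianceExplained)

#' @export
#' @describeIn Karyotype-class compact display of copies, sex and transgene.
setMethod("show", "Karyotype", function(object) {
  cat("Karyotype <", object@label, ">: ", object@sex,
      if (object@msl2) " + MSL2 transgene", "\n", sep = "")
  print(object@copies)
})

#' @export
#' @describeIn EffectModel-class display global factors and gene count.
setMethod("show", "EffectModel", function(object) {
  cat("EffectModel for", length(object@geneIds), "genes\n")
  cat("  inverse dosage response:",
      if (object@inverseDosage) "on (2/c)" else "off", "\n")
  cat("  msl2Factor:", format(object@msl2Factor, digits = 4),
      " sexBiasMult:", object@sexBiasMult, "\n")
  if (length(object@batchLog2Shift))
    cat("  batch log2 shifts:",
        paste(names(object@batchLog2Shift), "=",
              object@batchLog2Shift, collapse = ", "), "\n")
})

#' @export
#' @describeIn RatioDistribution-class display bin structure and modal peak.
setMethod("show", "RatioDistribution", function(object) {
  w <- diff(object@breaks)[1]
  cat("RatioDistribution:", length(object@counts), "bins of width",
      format(w, digits = 3), "on [", object@breaks[1], ",",
      object@breaks[length(object@breaks)], ")\n")
  cat("  n =", object@n, "in range;", object@overflow, "overflow;",
      if (object@percent) "percentages" else "raw frequencies", "\n")
  if (any(object@counts > 0))
    cat("  modal bin center:", format(modalPeak(object), digits = 4), "\n")
})

#' @export
#' @describeIn ModuleSet-class display module sizes.
setMethod("show", "ModuleSet", function(object) {
  tab <- table(object@labels)
  ord <- order(-tab)
  cat("ModuleSet:", length(object@labels), "genes,",
      sum(names(tab) != "grey"), "modules (+ grey)\n")
  print(tab[ord])
  if (nrow(object@eigengenes) > 0)
    cat("Eigengenes computed for", nrow(object@eigengenes), "modules over",
        ncol(object@eigengenes), "samples\n")
})
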