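#' Write a simulated experiment to TSV files
#'
#' Writes `counts.tsv` (genes in rows, header of sample ids), `samples.tsv`
#' (sample sheet) and `annotation.tsv` into a directory.
#'
#' @param ae an [AneuploidyExperiment-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeExperimentTSV <- function(ae, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fCounts <- file.path(dir, "counts.tsv")
  fSamples <- file.path(dir, "samples.tsv")
  fAnn <- file.path(dir, "annotation.tsv")
  cts <- assay(ae, "counts")
  utils::write.table(data.frame(gene_id = rownames(cts), cts,
                                check.names = FALSE),
                     fCounts, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sampleSheet(ae), fSamples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geneAnnotation(ae), fAnn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = fCounts, samples = fSamples, annotation = fAnn))
}

#' Read an experiment from TSV files
#'
#' Counterpart of [writeExperimentTSV()].
#'
#' @param countsFile counts TSV (first column gene_id).
#' @param samplesFile sample sheet TSV (first column sample_id, plus
#'   genotype, sex, batch, replicate).
#' @param annotationFile gene annotation TSV (gene_id, arm, position, ...).
#' @return an [AneuploidyExperiment-class].
#' @export
readExperimentTSV <- function(countsFile, samplesFile, annotationFile) {
  cts <- utils::read.delim(countsFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rn <- cts[[1]]
  cts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(cts) <- rn
  storage.mode(cts) <- "integer"
  ss <- utils::read.delim(samplesFile, stringsAsFactors = FALSE)
  rownames(ss) <- ss[[1]]
  ss <- ss[colnames(cts), -1, drop = FALSE]
  ann <- utils::read.delim(annotationFile, stringsAsFactors = FALSE)
  rownames(ann) <- ann$gene_id
  ann <- ann[rownames(cts), setdiff(colnames(ann), "gene_id"), drop = FALSE]
  AneuploidyExperiment(cts, ann, ss)
}

#' Simulate an experiment from a YAML configuration
#'
#' The configuration lists the genome (genes per arm and label fractions),
#' the effect-model parameters, and the design (one entry per genotype with
#' sex, varied arm, copies, msl2, replicates and batch). Any omitted value
#' falls back to the package default.
#'
#' @param path YAML file path.
#' @param seed integer seed overriding the config's `seed` (optional).
#' @return an [AneuploidyExperiment-class].
#' @export
simulateFromConfig <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed else 1L
  g <- cfg$genome
  ann <- buildGenome(unlist(g$n_genes_per_arm),
                     fracSexBiased = g$frac_sex_biased %||% 0.2,
                     fracTF = g$frac_tf %||% 0.05,
                     fracResponsive = g$frac_responsive %||% 0.8,
                     seed = seed)
  m <- cfg$model %||% list()
  model <- effectModel(ann,
                       meanlog = m$meanlog %||% 3,
                       sdlog = m$sdlog %||% 1.5,
                       dispShape = m$disp_shape %||% 2,
                       dispScale = m$disp_scale %||% 0.025,
                       inverseDosage = m$inverse_dosage %||% TRUE,
                       msl2Factor = m$msl2_factor %||% (2 / 3),
                       sexBiasMult = m$sex_bias_mult %||% 4,
                       batchLog2Shift = unlist(m$batch_log2_shift) %||% numeric(),
                       seed = seed)
  designs <- lapply(cfg$design, function(d) {
    k <- karyotype(d$sex, variedArm = d$varied_arm,
                   copies = d$copies %||% 3L, msl2 = isTRUE(d$msl2))
    simDesign(k, nReps = d$replicates %||% 3L, batch = d$batch %||% "b1")
  })
  simulateCounts(ann, model, designs,
                 librarySize = as.numeric(cfg$library_size %||% 5e6),
                 seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
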