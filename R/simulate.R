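#' Describe one simulated sample group
#'
#' @param karyotype a [Karyotype-class].
#' @param nReps number of biological replicates (>= 1).
#' @param batch batch identifier.
#' @return a design element for [simulateCounts()].
#' @export
simDesign <- function(karyotype, nReps = 3L, batch = "b1") {
  stopifnot(is(karyotype, "Karyotype"))
  if (nReps < 1) stop("nReps must be >= 1")
  list(karyotype = karyotype, nReps = as.integer(nReps),
       batch = as.character(batch))
}

#' Simulate aneuploid RNA-seq counts
#'
#' Draws negative-binomial counts per gene and sample with mean proportional
#' to the gene's expected expression (baseline abundance times the
#' karyotype's multiplicative dosage/MSL2/sex factors, times any batch
#' factors); within each sample the means are scaled so their sum equals the
#' library size, i.e. each sample sequences `librarySize` reads in
#' expectation. Dispersion 0 falls back to Poisson. A fixed seed reproduces
#' the matrix exactly.
#'
#' @param annotation gene annotation from [buildGenome()].
#' @param model an [EffectModel-class].
#' @param designs list of design elements from [simDesign()].
#' @param librarySize nominal reads per sample (default 5e6).
#' @param seed integer seed.
#' @return an [AneuploidyExperiment-class] (counts assay, annotation in
#'   rowData, sample sheet in colData).
#' @examples
#' ann <- buildGenome(c(X = 20, `2L` = 20), seed = 1)
#' m <- effectModel(ann, seed = 1)
#' ae <- simulateCounts(ann, m, list(
#'   simDesign(karyotype("female")), simDesign(karyotype("female", "2L"))),
#'   librarySize = 1e5, seed = 7)
#' ae
#' @export
simulateCounts <- function(annotation, model, designs, librarySize = 5e6,
                           seed = 1L) {
  if (length(designs) == 0) stop("designs must contain at least one group")
  if (librarySize <= 0) stop("librarySize must be positive")
  if (!identical(annotation$gene_id, model@geneIds))
    stop("annotation and model describe different genes")

  nG <- nrow(annotation)
  old <- .Random.seed.exists()
  set.seed(seed)
  cols <- list(); meta <- list()
  for (d in designs) {
    k <- d$karyotype
    f <- .expressionFactor(annotation, k, model)
    mu <- model@baselineMean * f
    if (sum(mu) > 0) mu <- mu / sum(mu) * librarySize
    if (d$batch %in% names(model@batchLog2Shift))
      mu <- mu * 2^model@batchLog2Shift[[d$batch]]
    if (d$batch %in% names(model@batchScale))
      mu <- mu * model@batchScale[[d$batch]]
    for (r in seq_len(d$nReps)) {
      y <- integer(nG)
      pos <- mu > 0
      alpha <- model@dispersion
      nbi <- pos & alpha > 0
      poi <- pos & alpha == 0
      if (any(nbi))
        y[nbi] <- stats::rnbinom(sum(nbi), mu = mu[nbi], size = 1 / alpha[nbi])
      if (any(poi))
        y[poi] <- stats::rpois(sum(poi), lambda = mu[poi])
      sid <- sprintf("%s_%s_r%d", k@label, d$batch, r)
      cols[[sid]] <- y
      meta[[sid]] <- data.frame(genotype = k@label, sex = k@sex,
                                batch = d$batch, replicate = r,
                                msl2 = k@msl2, stringsAsFactors = FALSE)
    }
  }
  .restore.seed(old)

  counts <- do.call(cbind, cols)
  rownames(counts) <- annotation$gene_id
  storage.mode(counts) <- "integer"
  cd <- do.call(rbind, meta)
  rownames(cd) <- colnames(counts)
  rd <- annotation[, setdiff(colnames(annotation), "gene_id"), drop = FALSE]
  rownames(rd) <- annotation$gene_id
  AneuploidyExperiment(counts, rd, cd)
}

#' Construct an AneuploidyExperiment from components
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param rowData gene annotation (arm, position, ...), rows parallel to
#'   `counts`.
#' @param colData sample sheet (genotype, sex, batch, replicate), rows
#'   parallel to columns of `counts`.
#' @return an [AneuploidyExperiment-class].
#' @export
AneuploidyExperiment <- function(counts, rowData, colData) {
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rowData, colData = colData)
  new("AneuploidyExperiment", se)
}
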