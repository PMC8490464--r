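#' Construct a generative effect model
#'
#' Draws per-gene baseline means from a log-normal distribution on the CPM
#' scale and per-gene NB dispersions from a gamma distribution, and fixes the
#' global multiplicative factors of the dosage-effect model.
#'
#' Baseline allocation mirrors a robust property of measured aneuploid
#' transcriptomes: per-gene expression ratios are compositional (CPM columns
#' are renormalized to a fixed total), so measured distributions can only
#' peak at the theoretical dosage ratios when the bulk of the library mass is
#' dosage-insensitive. The model therefore reserves the top baseline draws
#' for a housekeeping-like core -- non-responsive, non-sex-biased genes on
#' the arms never dosage-varied in the designs -- and multiplies them by
#' `hkBoost`, while all remaining genes share the lower draws at random.
#' Highly expressed housekeeping transcripts dominating the library (and
#' being buffered against trans-acting dosage responses) is both what real
#' libraries look like and the only composition under which CPM-scale ratio
#' distributions can peak at 3/2, 2/3 and 1 as observed.
#'
#' @param annotation gene annotation from [buildGenome()].
#' @param meanlog,sdlog log-normal parameters of the baseline CPM (defaults
#'   3 and 1.5).
#' @param dispShape,dispScale gamma parameters of the per-gene dispersion
#'   (defaults shape 4, scale 0.00125: mean 0.005, the replicate tightness of
#'   pooled whole-animal RNA-seq from isogenic lines).
#' @param hkBoost baseline multiplier of the housekeeping-like core (default
#'   15; the core then carries most of the library, as the top-expressed
#'   genes do in real libraries).
#' @param hkArms arms hosting the housekeeping core (default 2R, 3L, 3R, 4 --
#'   the arms never dosage-varied in the study designs).
#' @param inverseDosage logical; `FALSE` disables the trans inverse-dosage
#'   response (cis-only model).
#' @param msl2Factor trans-repression factor applied to responsive genes in
#'   MSL2-transgene females (default 2/3; males keep 1).
#' @param sexBiasMult multiplier for sex-biased genes in their biased sex
#'   (default 4).
#' @param batchLog2Shift named numeric, additive log2 offset per batch
#'   (default none).
#' @param batchScale named numeric, multiplicative scale factor per batch
#'   (default none).
#' @param seed integer seed for the per-gene draws.
#' @return an [EffectModel-class].
#' @examples
#' ann <- buildGenome(c(X = 50, `2L` = 50), seed = 1)
#' effectModel(ann, seed = 1)
#' @export
effectModel <- function(annotation, meanlog = 3, sdlog = 1.5,
                        dispShape = 4, dispScale = 0.00125,
                        inverseDosage = TRUE, msl2Factor = 2 / 3,
                        sexBiasMult = 4, hkBoost = 15,
                        hkArms = c("2R", "3L", "3R", "4"),
                        batchLog2Shift = numeric(), batchScale = numeric(),
                        seed = 1L) {
  n <- nrow(annotation)
  old <- .Random.seed.exists()
  set.seed(seed)
  draws <- sort(stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog))
  ## the housekeeping core takes the top order statistics (boosted); all
  ## other genes share the remaining draws at random
  core <- which(!annotation$responsive &
                  annotation$sex_bias_truth == "none" &
                  annotation$arm %in% hkArms)
  rest <- setdiff(seq_len(n), core)
  mu <- numeric(n)
  mu[rest[sample.int(length(rest))]] <- draws[seq_along(rest)]
  mu[core[sample.int(length(core))]] <-
    draws[length(rest) + seq_along(core)] * hkBoost
  alpha <- stats::rgamma(n, shape = dispShape, scale = dispScale)
  .restore.seed(old)
  if (length(batchScale) == 0 && length(batchLog2Shift) > 0)
    batchScale <- setNames(rep(1, length(batchLog2Shift)),
                           names(batchLog2Shift))
  new("EffectModel", geneIds = annotation$gene_id, baselineMean = mu,
      dispersion = alpha, inverseDosage = inverseDosage,
      msl2Factor = msl2Factor, sexBiasMult = sexBiasMult,
      batchLog2Shift = batchLog2Shift, batchScale = batchScale)
}

## Per-gene multiplicative expression factor of a karyotype relative to the
## matched diploid of the same sex. The building blocks:
##   cis: copies/diploid-copies on the gene's own arm;
##   trans inverse: prod over varied arms of diploid-copies/copies, for
##     responsive genes (2/3 in a trisomy);
##   MSL2: msl2Factor for responsive genes in transgene females, 1 in males;
##   sex bias: sexBiasMult for genes biased toward the karyotype's sex.
.expressionFactor <- function(annotation, k, model) {
  if (!all(annotation$arm %in% .ARMS))
    stop("unknown arm(s) in annotation: ",
         paste(unique(setdiff(annotation$arm, .ARMS)), collapse = ", "))
  base <- .diploidCopies(k@sex)
  cp <- base
  cp[names(k@copies)] <- k@copies
  cis <- cp[annotation$arm] / base[annotation$arm]
  varied <- names(cp)[cp != base]
  inv <- 1
  if (model@inverseDosage && length(varied) > 0)
    inv <- prod(base[varied] / cp[varied])
  f <- unname(cis)
  f[annotation$responsive] <- f[annotation$responsive] * inv
  if (k@msl2 && k@sex == "female")
    f[annotation$responsive] <- f[annotation$responsive] * model@msl2Factor
  biased <- annotation$sex_bias_truth == k@sex
  f[biased] <- f[biased] * model@sexBiasMult
  f
}

#' Analytic expected expression ratio
#'
#' The theoretical per-gene ratio of expression in an experimental karyotype
#' over a control karyotype under the multiplicative dosage-effect model:
#' the product of the cis gene-dosage factor (c/2 on the varied arm), the
#' trans inverse-dosage factor (2/c for responsive genes), the female-specific
#' MSL2 repression factor, and sex-bias terms, for the experimental karyotype
#' divided by the same product for the control. This is the oracle every
#' pipeline stage is expected to recover: e.g. 3/2 x 2/3 = 1 on the varied arm
#' of a trisomy (dosage compensation) and 2/3 for responsive trans genes.
#'
#' @param annotation gene annotation (one or more rows).
#' @param k experimental [Karyotype-class].
#' @param model an [EffectModel-class].
#' @param control control [Karyotype-class]; defaults to the matched diploid
#'   of the same sex.
#' @return numeric vector of expected ratios, one per annotation row.
#' @examples
#' ann <- buildGenome(c(X = 4, `2L` = 4), fracResponsive = 1, seed = 1)
#' m <- effectModel(ann, seed = 1)
#' expectedRatio(ann, karyotype("female", "2L"), m)  # 1 on 2L, 2/3 on X
#' @export
expectedRatio <- function(annotation, k, model, control = matchedDiploid(k)) {
  if (k@sex != control@sex)
    stop("control must be the matched diploid of the same sex")
  .expressionFactor(annotation, k, model) /
    .expressionFactor(annotation, control, model)
}
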