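#' Build a synthetic fly-like gene annotation
#'
#' Lays out genes on the six chromosome arms (X, 2L, 2R, 3L, 3R, 4) with
#' ordinal positions, and assigns truth labels used by the simulator and by
#' recovery tests: sex-bias class (split evenly between female- and
#' male-biased), transcription-factor flags, and responsiveness to the trans
#' inverse-dosage effect.
#'
#' Label quotas are exact: `round(frac * n)` genes per label, sampled without
#' replacement, so a fixed seed yields identical annotations.
#'
#' @param nGenesPerArm named integer vector of gene counts per arm; names must
#'   be among X, 2L, 2R, 3L, 3R, 4 and counts >= 1.
#' @param fracSexBiased fraction of genes with a sex-biased expression truth
#'   label, split evenly between female- and male-biased (default 0.2).
#' @param fracTF fraction flagged as transcription factors (default 0.05).
#' @param fracResponsive fraction participating in the trans inverse-dosage
#'   response (default 0.8; real ratio distributions keep a ratio-1 shoulder
#'   of non-responding genes).
#' @param seed integer seed; the annotation is deterministic given it.
#' @return `data.frame` with columns gene_id, arm, position, sex_bias_truth
#'   (`"female"`, `"male"`, `"none"`), is_tf, responsive.
#' @examples
#' ann <- buildGenome(c(X = 20, `2L` = 20), fracTF = 0.1, seed = 1)
#' table(ann$arm)
#' @export
buildGenome <- function(nGenesPerArm, fracSexBiased = 0.2, fracTF = 0.05,
                        fracResponsive = 0.8, seed = 1L) {
  nGenesPerArm <- unlist(nGenesPerArm)
  if (is.null(names(nGenesPerArm)) ||
      !all(names(nGenesPerArm) %in% .ARMS))
    stop("nGenesPerArm must be named with arms among: ",
         paste(.ARMS, collapse = ", "))
  if (any(nGenesPerArm < 1))
    stop("gene counts per arm must be >= 1")
  for (f in c(fracSexBiased, fracTF, fracResponsive))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")

  arms <- intersect(.ARMS, names(nGenesPerArm))
  arm <- rep(arms, nGenesPerArm[arms])
  position <- unlist(lapply(nGenesPerArm[arms], seq_len), use.names = FALSE)
  gene_id <- sprintf("g%s_%04d", arm, position)
  n <- length(gene_id)

  old <- .Random.seed.exists()
  set.seed(seed)
  sex_bias_truth <- rep("none", n)
  nsb <- round(fracSexBiased * n)
  if (nsb > 0) {
    idx <- sample.int(n, nsb)
    nf <- ceiling(nsb / 2)
    sex_bias_truth[idx[seq_len(nf)]] <- "female"
    if (nsb > nf) sex_bias_truth[idx[(nf + 1):nsb]] <- "male"
  }
  is_tf <- rep(FALSE, n)
  ntf <- round(fracTF * n)
  if (ntf > 0) is_tf[sample.int(n, ntf)] <- TRUE
  responsive <- rep(FALSE, n)
  nr <- round(fracResponsive * n)
  if (nr > 0) responsive[sample.int(n, nr)] <- TRUE
  .restore.seed(old)

  data.frame(gene_id = gene_id, arm = arm, position = position,
             sex_bias_truth = sex_bias_truth, is_tf = is_tf,
             responsive = responsive, stringsAsFactors = FALSE)
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore.seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Construct a karyotype
#'
#' @param sex `"female"` or `"male"`.
#' @param variedArm optional arm whose copy number deviates from the matched
#'   diploid (e.g. `"2L"` for trisomy 2L, `"X"` for a metafemale).
#' @param copies copy number of `variedArm` (default 3).
#' @param msl2 logical, ectopic MSL2 transgene.
#' @param label genotype label; a default is derived from the arguments.
#' @return a [Karyotype-class].
#' @examples
#' karyotype("female", "2L")              # trisomy 2L female
#' karyotype("female", "X", msl2 = TRUE)  # MSL2-metafemale
#' @export
karyotype <- function(sex = c("female", "male"), variedArm = NULL,
                      copies = 3L, msl2 = FALSE, label = NULL) {
  sex <- match.arg(sex)
  cp <- .diploidCopies(sex)
  if (!is.null(variedArm)) {
    if (!variedArm %in% .ARMS)
      stop("unknown arm: ", variedArm)
    cp[variedArm] <- as.integer(copies)
  }
  if (is.null(label)) {
    base <- if (is.null(variedArm)) "diploid"
            else if (variedArm == "X" && copies == 3L) "metafemale"
            else paste0("trisomy", variedArm)
    label <- paste0(if (msl2) "MSL2-" else "", base, "_",
                    if (sex == "female") "F" else "M")
  }
  new("Karyotype", copies = cp, sex = sex, msl2 = msl2, label = label)
}

.diploidCopies <- function(sex) {
  cp <- setNames(rep(2L, length(.ARMS)), .ARMS)
  if (sex == "male") cp["X"] <- 1L
  cp
}

#' Matched diploid control of a karyotype
#'
#' @param k a [Karyotype-class].
#' @return the diploid [Karyotype-class] of the same sex, no transgene.
#' @export
matchedDiploid <- function(k) {
  stopifnot(is(k, "Karyotype"))
  karyotype(k@sex)
}

#' The study's genotype panel
#'
#' Convenience list of the karyotypes analysed throughout: diploid female and
#' male, trisomy-2L female and male, their MSL2-transgene counterparts, and
#' the metafemale (XXX) pair.
#'
#' @return named list of [Karyotype-class] objects.
#' @export
genotypePanel <- function() {
  ks <- list(
    karyotype("female"),
    karyotype("male"),
    karyotype("female", "2L"),
    karyotype("male", "2L"),
    karyotype("female", "2L", msl2 = TRUE),
    karyotype("male", "2L", msl2 = TRUE),
    karyotype("female", "X"),
    karyotype("female", "X", msl2 = TRUE))
  names(ks) <- vapply(ks, function(k) k@label, character(1))
  ks
}
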