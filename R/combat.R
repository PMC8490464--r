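.rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Empirical-Bayes batch adjustment of log expression
#'
#' Parametric empirical-Bayes location/scale batch correction for log-scale
#' expression matrices. Per gene, the data are standardized under a model
#' with batch and biological-group terms; per-batch location (gamma) and
#' scale (delta^2) parameters are estimated and shrunk toward parametric
#' priors (normal for gamma, inverse-gamma for delta^2, hyperparameters by
#' method of moments), the shrunken effects are removed, and the data are
#' returned to the original scale. As a final step each gene is re-centred
#' so its grand mean across all samples is exactly preserved.
#'
#' A single-batch input is returned unchanged: there is nothing to adjust.
#'
#' @param x numeric matrix, genes x samples, on a log scale (e.g.
#'   `log2(CPM + 0.5)`).
#' @param batch vector of batch labels, length `ncol(x)`; at least two
#'   batches with two or more samples each are required for adjustment.
#' @param group optional vector of biological group labels retained as
#'   covariates so that group signal is not absorbed into batch effects.
#' @param tol convergence tolerance of the EB iteration (default 1e-6).
#' @return adjusted matrix on the same log scale.
#' @export
combatAdjust <- function(x, batch, group = NULL, tol = 1e-6) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x))
    stop("batch must label every sample")
  levs <- unique(batch)
  nPer <- table(factor(batch, levels = levs))
  if (any(nPer == 0))
    stop("batch level(s) with no samples: ",
         paste(names(nPer)[nPer == 0], collapse = ", "))
  if (length(levs) == 1L)
    return(x)
  if (any(nPer < 2))
    stop("each batch needs at least 2 samples")

  nb <- length(levs)
  N <- ncol(x)
  batchDesign <- stats::model.matrix(~ 0 + factor(batch, levels = levs))
  colnames(batchDesign) <- levs
  design <- batchDesign
  if (!is.null(group)) {
    gf <- factor(as.character(group))
    if (nlevels(gf) > 1) {
      gm <- stats::model.matrix(~ gf)[, -1, drop = FALSE]
      design <- cbind(batchDesign, gm)
    }
  }
  if (qr(design)$rank < ncol(design))
    stop("batch is confounded with the group covariates; ",
         "no residual degrees of freedom to estimate batch effects")

  ## gene-wise OLS fit: coefficients are (p x G)
  B <- solve(crossprod(design), crossprod(design, t(x)))
  grand <- crossprod(as.numeric(nPer) / N, B[seq_len(nb), , drop = FALSE])
  resid <- x - t(design %*% B)
  varPooled <- rowSums(resid^2) / N
  varPooled <- pmax(varPooled, 1e-12)

  covDesign <- design
  covDesign[, seq_len(nb)] <- 0
  standMean <- matrix(grand, nrow(x), N) + t(covDesign %*% B)
  sdVec <- sqrt(varPooled)
  sData <- (x - standMean) / sdVec

  gammaHat <- matrix(0, nb, nrow(x))
  deltaHat <- matrix(0, nb, nrow(x))
  for (i in seq_len(nb)) {
    sel <- batch == levs[i]
    gammaHat[i, ] <- rowMeans(sData[, sel, drop = FALSE])
    deltaHat[i, ] <- .rowVars(sData[, sel, drop = FALSE])
  }
  deltaHat <- pmax(deltaHat, 1e-12)

  gammaStar <- gammaHat
  deltaStar <- deltaHat
  for (i in seq_len(nb)) {
    sel <- batch == levs[i]
    n <- sum(sel)
    gBar <- mean(gammaHat[i, ])
    t2 <- stats::var(gammaHat[i, ])
    m <- mean(deltaHat[i, ]); s2 <- stats::var(deltaHat[i, ])
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    gOld <- gammaHat[i, ]; dOld <- deltaHat[i, ]
    sub <- sData[, sel, drop = FALSE]
    repeat {
      gNew <- (n * t2 * gammaHat[i, ] + dOld * gBar) / (n * t2 + dOld)
      sum2 <- rowSums((sub - gNew)^2)
      dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
      change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-12),
                    abs(dNew - dOld) / pmax(abs(dOld), 1e-12))
      gOld <- gNew; dOld <- dNew
      if (change < tol) break
    }
    gammaStar[i, ] <- gOld
    deltaStar[i, ] <- dOld
  }

  out <- sData
  for (i in seq_len(nb)) {
    sel <- batch == levs[i]
    out[, sel] <- (sData[, sel, drop = FALSE] - gammaStar[i, ]) /
      sqrt(deltaStar[i, ])
  }
  out <- out * sdVec + standMean
  ## exact grand-mean restoration per gene
  out + (rowMeans(x) - rowMeans(out))
}
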