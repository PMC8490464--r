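#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median across
#' all-positive genes of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts non-negative count matrix, genes x samples, or an
#'   [AneuploidyExperiment-class].
#' @return numeric vector of size factors, one per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  if (is(counts, "AneuploidyExperiment")) counts <- assay(counts, "counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with all-positive counts; prefilter or deepen sampling")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logGeo)))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A compact NB differential-expression workflow: median-of-ratios size
#' factors, per-gene method-of-moments dispersion, a local dispersion trend
#' (running median over log mean), shrinkage of the gene dispersion toward
#' the trend (geometric mean, weight 0.5), an NB log-link GLM fitted by
#' iteratively reweighted least squares with size-factor offsets, and a Wald
#' test of the group log2 fold change against a normal reference.
#'
#' @param counts count matrix (genes x samples) or
#'   [AneuploidyExperiment-class].
#' @param group vector with exactly two levels, length `ncol(counts)`;
#'   fold changes are second factor level over first (alphabetical for
#'   character input, as in `factor()`).
#' @param sizeFactors optional per-sample normalization factors; computed by
#'   [medianRatioSizeFactors()] when missing.
#' @param maxit IRLS iteration cap (default 100); non-converged genes get
#'   `NA` p-values.
#' @return `data.frame` with gene_id, baseMean, log2FoldChange, lfcSE, stat,
#'   pvalue, padj (Benjamini-Hochberg), converged.
#' @export
nbWaldTest <- function(counts, group, sizeFactors = NULL, maxit = 100L) {
  if (is(counts, "AneuploidyExperiment")) counts <- assay(counts, "counts")
  gf <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(gf) != 2) stop("group must have exactly two levels")
  if (any(table(gf) < 2)) stop("each group needs at least 2 samples")
  if (length(gf) != ncol(counts)) stop("group must label every sample")
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)

  x <- as.numeric(gf) - 1
  norm <- sweep(counts, 2, sizeFactors, "/")
  baseMean <- rowMeans(norm)

  alpha <- .dispersionEstimate(norm, gf, baseMean, sizeFactors)

  fit <- .nbIRLS(counts, x, log(sizeFactors), alpha, maxit)
  lfc <- fit$beta1 / log(2)
  se <- fit$se1 / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  pvalue[!fit$converged] <- NA_real_
  data.frame(gene_id = rownames(counts), baseMean = baseMean,
             log2FoldChange = lfc, lfcSE = se, stat = stat,
             pvalue = pvalue, padj = bhAdjust(pvalue),
             converged = fit$converged,
             row.names = rownames(counts), stringsAsFactors = FALSE)
}

## method-of-moments gene dispersions, local running-median trend on log
## mean, and weight-0.5 geometric shrinkage toward the trend. Both the
## per-gene log estimate and the running median track quantiles of a
## right-skewed (approximately alpha * chisq_d / d) sampling distribution
## and so sit below the true dispersion; the final estimate multiplies in
## the corresponding Gaussian-limit log-bias corrections (df = N - 2),
## without which the Wald test is anticonservative at small n.
.dispersionEstimate <- function(norm, gf, baseMean, sizeFactors) {
  lev <- levels(gf)
  nG <- nrow(norm)
  ss <- matrix(0, nG, 2); ns <- integer(2)
  for (j in 1:2) {
    sub <- norm[, gf == lev[j], drop = FALSE]
    ns[j] <- ncol(sub)
    ss[, j] <- rowSums((sub - rowMeans(sub))^2)
  }
  wVar <- rowSums(ss) / (sum(ns) - 2L)
  xi <- baseMean * mean(1 / sizeFactors)  # Poisson (shot-noise) component
  aMoM <- pmax((wVar - xi) / baseMean^2, 1e-8)
  aMoM[baseMean <= 0] <- 1e-8

  ok <- baseMean > 0
  o <- order(baseMean[ok])
  la <- log(aMoM[ok])[o]
  k <- max(5L, min(201L, 2L * floor(0.05 * sum(ok)) + 1L))
  if (k %% 2 == 0) k <- k + 1L
  trendSorted <- if (sum(ok) >= k)
    stats::runmed(la, k, endrule = "median") else rep(stats::median(la), sum(ok))
  trend <- rep(stats::median(la), length(aMoM))
  trend[which(ok)[o]] <- trendSorted
  d <- sum(ns) - 2L
  ## the gene term is floored two sampling SDs below the trend: moment
  ## estimates far under the trend are sampling zeros, and letting them
  ## drag the shrunken dispersion toward Poisson makes the test liberal
  aG <- pmax(aMoM, exp(trend - 2 * sqrt(trigamma(d / 2))))
  ## location bias of the two log-scale components (mean bias of the gene
  ## term, median bias of the running-median trend), plus a Jensen term for
  ## the sampling variance the weight-0.5 gene component carries into the
  ## Wald denominator
  corr <- exp(-0.5 * (digamma(d / 2) - log(d / 2)) -
                0.5 * log(stats::qchisq(0.5, d) / d) +
                0.125 * trigamma(d / 2))
  exp(0.5 * log(aG) + 0.5 * trend) * corr
}

## vectorized IRLS across genes for the model log mu = b0 + b1 x + offset,
## x a 0/1 group indicator; returns Wald SE of b1 from the Fisher
## information
.nbIRLS <- function(counts, x, logSf, alpha, maxit) {
  nG <- nrow(counts); nS <- ncol(counts)
  y <- counts
  off <- matrix(logSf, nG, nS, byrow = TRUE)
  nA <- sum(x == 0); nB <- sum(x == 1)
  muA0 <- (rowSums(sweep(y[, x == 0, drop = FALSE], 2,
                         exp(logSf[x == 0]), "/")) + 0.5) / nA
  muB0 <- (rowSums(sweep(y[, x == 1, drop = FALSE], 2,
                         exp(logSf[x == 1]), "/")) + 0.5) / nB
  b0 <- log(muA0); b1 <- log(muB0) - log(muA0)
  active <- rep(TRUE, nG)
  xm <- matrix(x, nG, nS, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- sweep(xm * b1, 1, b0, "+") + off
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    R <- (y - mu) / (1 + alpha * mu)
    U0 <- rowSums(R); U1 <- rowSums(R * xm)
    A <- rowSums(W); B <- rowSums(W * xm)
    ## solve the 2x2 Fisher system [A B; B B] [d0; d1] = [U0; U1]
    det <- pmax(A * B - B^2, 1e-300)
    d1 <- (A * U1 - B * U0) / det
    d0 <- (U0 - B * d1) / A
    step <- pmax(abs(d0), abs(d1))
    upd <- active & step > 1e-10
    b0[upd] <- b0[upd] + d0[upd]
    b1[upd] <- b1[upd] + d1[upd]
    b1 <- pmin(pmax(b1, -30), 30)
    active <- active & step > 1e-10
    if (!any(active)) break
  }
  eta <- sweep(xm * b1, 1, b0, "+") + off
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  A <- rowSums(W); B <- rowSums(W * xm)
  det <- pmax(A * B - B^2, 1e-300)
  list(beta1 = b1, se1 = sqrt(A / det), converged = !active)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' capped at 1. `NA` p-values propagate as `NA`.
#'
#' @param p numeric p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify sex-biased genes from a female-vs-male test
#'
#' Genes with `padj < alpha` are female-biased when the (female over male)
#' log2 fold change is positive and male-biased when negative; all other
#' genes, including those with missing `padj`, are non-biased.
#'
#' @param de `data.frame` from [nbWaldTest()] run on diploid female vs male
#'   samples, fold change oriented female over male.
#' @param alpha significance level on `padj` (default 0.05).
#' @return named character vector: `"female_biased"`, `"male_biased"` or
#'   `"non_biased"` per gene.
#' @export
classifySexBias <- function(de, alpha = 0.05) {
  if (anyNA(de$padj))
    warning(sum(is.na(de$padj)), " gene(s) without padj set to non_biased")
  cls <- rep("non_biased", nrow(de))
  sig <- !is.na(de$padj) & de$padj < alpha
  cls[sig & de$log2FoldChange > 0] <- "female_biased"
  cls[sig & de$log2FoldChange < 0] <- "male_biased"
  names(cls) <- de$gene_id
  cls
}

#' Gene-set overlap enrichment test
#'
#' One-sided hypergeometric (Fisher) enrichment of the intersection of two
#' gene sets within a universe, with the Venn counts.
#'
#' @param setA,setB character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return list with sizeA, sizeB, intersection, universe, p.value.
#' @export
overlapTest <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be contained in the universe")
  nU <- length(universe); nA <- length(setA); nB <- length(setB)
  k <- length(intersect(setA, setB))
  p <- stats::phyper(k - 1, nA, nU - nA, nB, lower.tail = FALSE)
  list(sizeA = nA, sizeB = nB, intersection = k, universe = nU,
       p.value = min(p, 1))
}

#' Read a protein-protein interaction edge table
#'
#' Three-column TSV (node, node, combined score), the STRING export dialect;
#' scores on a 0-1000 scale are normalized to `[0, 1]`. Self-loops are
#' dropped.
#'
#' @param path TSV file path (a header line is detected and skipped if the
#'   third field is not numeric).
#' @return an undirected [igraph::graph] with edge attribute
#'   `combined_score` in `[0, 1]`.
#' @export
readPPIGraph <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  hasHeader <- is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.delim(path, header = hasHeader,
                          stringsAsFactors = FALSE)[, 1:3]
  colnames(df) <- c("a", "b", "combined_score")
  df <- df[df$a != df$b, , drop = FALSE]
  if (nrow(df) && max(df$combined_score) > 1)
    df$combined_score <- df$combined_score / 1000
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Shortest-path neighbourhood of a seed gene in a PPI graph
#'
#' Breadth-first filter: keeps nodes whose unweighted shortest path from the
#' seed is at most `maxEdges` (e.g. under two edges in females, under three
#' in males) and the edges they induce.
#'
#' @param graph an undirected [igraph::graph].
#' @param seedNode node name present in the graph.
#' @param maxEdges maximum path length in edges (>= 0).
#' @return the induced [igraph::graph] subgraph.
#' @export
shortestPathFilter <- function(graph, seedNode, maxEdges) {
  if (!seedNode %in% igraph::V(graph)$name)
    stop("seed node '", seedNode, "' not present in graph")
  d <- igraph::distances(graph, v = seedNode, weights = NA)[1, ]
  keep <- names(d)[d <= maxEdges]
  igraph::induced_subgraph(graph, keep)
}
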