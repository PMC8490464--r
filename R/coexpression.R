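.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan")

#' Select the most highly expressed genes
#'
#' Keeps the `n` genes with the highest mean expression (the coexpression
#' analysis convention: the 10,000 genes with the highest average log
#' expression). Ties are broken by gene id.
#'
#' @param expr numeric matrix, genes x samples (log scale recommended).
#' @param n number of genes to keep (1 <= n <= nrow(expr)).
#' @return the row-subset matrix, original row order preserved.
#' @export
selectTopGenes <- function(expr, n = 10000L) {
  if (n < 1 || n > nrow(expr))
    stop("n must lie between 1 and the number of genes")
  m <- rowMeans(expr)
  ord <- order(-m, rownames(expr))
  keep <- sort(ord[seq_len(n)])
  expr[keep, , drop = FALSE]
}

#' Signed soft-threshold adjacency
#'
#' Pearson correlation across samples mapped to `[0, 1]` and raised to the
#' soft power: `a_ij = ((1 + cor_ij) / 2)^beta`. The study's soft powers are
#' 11 for the autosomal-aneuploidy design and 17 for the sex-chromosomal
#' design.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param beta soft threshold power (integer >= 1).
#' @return symmetric adjacency matrix in `[0, 1]`.
#' @export
signedAdjacency <- function(expr, beta = 11L) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  ((1 + r) / 2)^beta
}

#' Topological overlap matrix
#'
#' Network similarity combining direct adjacency and shared neighbours:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` (the sum excluding u in {i, j}, k the connectivity excluding the
#' diagonal), `TOM_ii = 1`.
#'
#' @param adj symmetric adjacency matrix in `[0, 1]`.
#' @return symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tomSimilarity <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a            # includes u = i and u = j terms, both 0
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect coexpression modules on a TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a fixed height; clusters smaller than `minModuleSize` are sent to
#' `"grey"` (unclustered). Modules are labelled with the colour convention
#' in decreasing size order (turquoise largest, then blue, brown, ...).
#'
#' The default cut height reflects the scale of TOM dissimilarities under
#' average linkage: unrelated gene groups join at heights around 0.97-1.00
#' (their topological overlap is near zero but never exactly zero), so the
#' cut must sit below that ceiling for uncorrelated genes to remain
#' unclustered while genuine modules, whose internal heights are far lower,
#' stay intact.
#'
#' @param tom TOM from [tomSimilarity()].
#' @param minModuleSize smallest retained module (default 30).
#' @param cutHeight static cut height on `1 - TOM` (default 0.95).
#' @return a [ModuleSet-class] (labels only; see [moduleEigengene()]).
#' @export
detectModules <- function(tom, minModuleSize = 30L, cutHeight = 0.95) {
  if (nrow(tom) < minModuleSize)
    stop("fewer genes than minModuleSize")
  if (is.null(rownames(tom)))
    rownames(tom) <- paste0("gene", seq_len(nrow(tom)))
  d <- stats::as.dist(1 - tom)
  if (max(d) - min(d) < 1e-12)
    warning("degenerate TOM: all dissimilarities equal")
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    if (length(keep) > length(.MODULE_COLORS))
      keep <- keep[seq_along(.MODULE_COLORS)]
    for (i in seq_along(keep))
      labels[cl == keep[i]] <- .MODULE_COLORS[i]
  }
  names(labels) <- rownames(tom)
  new("ModuleSet", labels = labels,
      eigengenes = matrix(numeric(), 0, 0),
      varianceExplained = setNames(numeric(), character()))
}

#' Module eigengenes
#'
#' For each non-grey module, the first principal component of the per-gene
#' z-scored module submatrix across samples, sign-oriented to correlate
#' positively with the module's mean expression profile, with the fraction
#' of variance it explains. A one-gene module's eigengene is that gene's
#' z-scored profile.
#'
#' @param expr numeric matrix, genes x samples (same genes as the module
#'   detection input).
#' @param modules a [ModuleSet-class] from [detectModules()].
#' @return the [ModuleSet-class] with `eigengenes` (modules x samples) and
#'   `varianceExplained` filled in.
#' @export
moduleEigengene <- function(expr, modules) {
  labs <- moduleLabels(modules)
  mods <- setdiff(unique(labs), "grey")
  mods <- mods[order(match(mods, .MODULE_COLORS))]
  if (!length(mods)) stop("no non-grey modules to summarize")
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labs)[labs == m]
    sub <- expr[genes, , drop = FALSE]
    z <- t(scale(t(sub)))
    if (nrow(z) == 1) {
      eg[m, ] <- z[1, ]
      ve[m] <- 1
      next
    }
    sv <- svd(z)
    v1 <- sv$v[, 1]
    if (stats::cor(v1, colMeans(z)) < 0) v1 <- -v1
    eg[m, ] <- v1
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  new("ModuleSet", labels = labs, eigengenes = eg, varianceExplained = ve)
}

#' Per-genotype eigengene summary
#'
#' Mean and t-based 95% confidence interval of each module eigengene within
#' each genotype. Genotypes with a single replicate get the mean only
#' (`ciLow`/`ciHigh` set `NA` and flagged).
#'
#' @param modules a [ModuleSet-class] with eigengenes computed.
#' @param genotype vector of genotype labels, one per sample (column of the
#'   eigengene matrix).
#' @param conf confidence level (default 0.95).
#' @return `data.frame` with module, genotype, n, mean, ciLow, ciHigh,
#'   ciAvailable.
#' @export
eigengeneSummary <- function(modules, genotype, conf = 0.95) {
  eg <- eigengenes(modules)
  if (nrow(eg) == 0) stop("eigengenes not computed; run moduleEigengene()")
  genotype <- as.character(genotype)
  if (length(genotype) != ncol(eg))
    stop("genotype must label every sample")
  out <- list()
  for (m in rownames(eg)) for (g in unique(genotype)) {
    v <- eg[m, genotype == g]
    n <- length(v)
    mu <- mean(v)
    if (n >= 2) {
      hw <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n)
      ci <- c(mu - hw, mu + hw); avail <- TRUE
    } else {
      ci <- c(NA_real_, NA_real_); avail <- FALSE
    }
    out[[length(out) + 1L]] <- data.frame(
      module = m, genotype = g, n = n, mean = mu,
      ciLow = ci[1], ciHigh = ci[2], ciAvailable = avail,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
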