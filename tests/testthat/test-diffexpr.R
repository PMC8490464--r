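test_that("median-of-ratios size factors match hand enumeration", {
  cts <- matrix(c(5L, 8L, 13L, 5L, 8L, 13L), 3, 2)
  rownames(cts) <- paste0("g", 1:3)
  expect_equal(unname(medianRatioSizeFactors(cts)), c(1, 1))

  cts2 <- cbind(cts[, 1], cts[, 1] * 2L)
  rownames(cts2) <- paste0("g", 1:3)
  sf <- medianRatioSizeFactors(cts2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # 3x2 toy: every ratio equals 1/sqrt(2) resp. sqrt(2)
  toy <- matrix(c(10L, 100L, 1L, 20L, 200L, 2L), 3, 2)
  rownames(toy) <- paste0("g", 1:3)
  expect_equal(unname(medianRatioSizeFactors(toy)),
               c(1 / sqrt(2), sqrt(2)))

  zero <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  expect_error(medianRatioSizeFactors(zero), "all-positive")
})

test_that("the NB Wald test is symmetric and exact on duplicated groups", {
  set.seed(41)
  G <- 300
  mu <- rlnorm(G, 5, 1)
  cts <- matrix(rnbinom(G * 6, mu = rep(mu, 6), size = 20), G, 6)
  rownames(cts) <- paste0("g", 1:G)

  dup <- cbind(cts[, 1:3], cts[, 1:3])
  deDup <- nbWaldTest(dup, rep(c("A", "B"), each = 3))
  expect_equal(max(abs(deDup$log2FoldChange)), 0)

  d1 <- nbWaldTest(cts, rep(c("A", "B"), each = 3))
  d2 <- nbWaldTest(cts, rep(c("B", "A"), each = 3))
  expect_lt(max(abs(d1$log2FoldChange + d2$log2FoldChange)), 1e-6)
  expect_lt(max(abs(d1$pvalue - d2$pvalue)), 1e-6)

  expect_error(nbWaldTest(cts, rep("A", 6)), "two levels")
  expect_error(nbWaldTest(cts, c("A", rep("B", 5))), "at least 2")
})

test_that("fold-change estimates track the reference NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  G <- 250
  mu <- rlnorm(G, 5, 1)
  mu2 <- mu * 2^rnorm(G, 0, 0.5)
  cts <- cbind(matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 10), G, 3),
               matrix(rnbinom(G * 3, mu = rep(mu2, 3), size = 10), G, 3))
  rownames(cts) <- paste0("g", 1:G)
  mine <- nbWaldTest(cts, rep(c("A", "B"), each = 3))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cts, data.frame(g = factor(rep(c("A", "B"), each = 3))), ~g)
  dds <- suppressMessages(DESeq2::DESeq(dds, fitType = "local",
                                        quiet = TRUE))
  ref <- DESeq2::results(dds)
  ok <- mine$converged & !is.na(ref$log2FoldChange)
  expect_gt(stats::cor(mine$log2FoldChange[ok], ref$log2FoldChange[ok]),
            0.99)
})

test_that("DE calls are monotone in alpha and padj dominates p", {
  set.seed(43)
  G <- 400
  mu <- rlnorm(G, 5, 1)
  mu2 <- mu; mu2[1:40] <- mu2[1:40] * 3
  cts <- cbind(matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 20), G, 3),
               matrix(rnbinom(G * 3, mu = rep(mu2, 3), size = 20), G, 3))
  rownames(cts) <- paste0("g", 1:G)
  de <- nbWaldTest(cts, rep(c("A", "B"), each = 3))
  expect_true(all(de$padj >= de$pvalue - 1e-12, na.rm = TRUE))
  nDE <- vapply(c(0.01, 0.05, 0.1),
                function(a) sum(de$padj < a, na.rm = TRUE), numeric(1))
  expect_true(all(diff(nDE) >= 0))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")

  set.seed(44)
  for (i in 1:40) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bruteBH(p))
  }
})

test_that("sex-bias classes follow the padj/direction rule and recover truth", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2FoldChange = c(-2, 1.5, 0.2, 3),
                   padj = c(0.049, 0.01, 0.2, NA))
  expect_warning(cls <- classifySexBias(de), "non_biased")
  expect_identical(unname(cls), c("male_biased", "female_biased",
                                  "non_biased", "non_biased"))

  # recovery on simulated diploid females vs males (fold change oriented
  # female over male via factor levels)
  ae <- tinyAE()
  ss <- sampleSheet(ae)
  sel <- ss$genotype %in% c("diploid_F", "diploid_M")
  cts <- assay(ae, "counts")[, sel]
  cts <- cts[rowSums(cts) >= 10, ]
  grp <- factor(ss$genotype[sel], levels = c("diploid_M", "diploid_F"))
  cls2 <- classifySexBias(nbWaldTest(cts, grp))
  truth <- geneAnnotation(ae)[names(cls2), "sex_bias_truth"]
  fb <- truth == "female"; mb <- truth == "male"; nb <- truth == "none"
  expect_gt(mean(cls2[fb] == "female_biased"), 0.9)
  expect_gt(mean(cls2[mb] == "male_biased"), 0.9)
  expect_gt(mean(cls2[nb] == "non_biased"), 0.9)
})

test_that("overlap enrichment equals exhaustive hypergeometric tails", {
  u <- paste0("g", 1:10)
  res <- overlapTest(u[1:4], u[c(1:3, 5, 6)], u)
  expect_identical(res$intersection, 3L)
  res2 <- overlapTest(u[1:4], u[1:5], u)
  expect_equal(res2$p.value, 5 / 210)
  expect_equal(res2$p.value, bruteHyper(4, 4, 5, 10))

  expect_equal(overlapTest(u[1:3], u[4:6], u)$p.value, 1)
  expect_equal(overlapTest(u, u[2:5], u)$p.value, 1)
  expect_error(overlapTest(c(u[1], "zz"), u[1:2], u), "contained")

  set.seed(45)
  for (i in 1:40) {
    nU <- sample(5:30, 1)
    uni <- paste0("x", seq_len(nU))
    A <- sample(uni, sample(1:nU, 1))
    B <- sample(uni, sample(1:nU, 1))
    res <- overlapTest(A, B, uni)
    expect_equal(res$p.value,
                 bruteHyper(res$intersection, length(A), length(B), nU),
                 tolerance = 1e-12)
  }
})

test_that("PPI graphs load, normalize scores and filter by shortest path", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("node1\tnode2\tcombined_score",
               "a\tb\t900", "b\tc\t800", "c\td\t700", "e\te\t500",
               "f\tg\t400"), tsv)
  g <- readPPIGraph(tsv)
  expect_true(all(igraph::E(g)$combined_score <= 1))
  expect_false(any(igraph::which_loop(g)))

  sub <- shortestPathFilter(g, "a", 2)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c"))
  expect_setequal(igraph::V(shortestPathFilter(g, "a", 0))$name, "a")
  # three-edge male rule reaches d; disconnected f/g never join
  expect_setequal(igraph::V(shortestPathFilter(g, "a", 3))$name,
                  c("a", "b", "c", "d"))
  expect_error(shortestPathFilter(g, "zz", 2), "not present")
})
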