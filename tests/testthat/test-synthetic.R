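test_that("buildGenome lays out genes deterministically with exact quotas", {
  a1 <- buildGenome(c(X = 10, `2L` = 10), fracSexBiased = 0, seed = 3)
  expect_true(all(a1$sex_bias_truth == "none"))
  expect_identical(a1, buildGenome(c(X = 10, `2L` = 10),
                                   fracSexBiased = 0, seed = 3))

  a2 <- buildGenome(c(`2L` = 100), fracTF = 0.1, seed = 1)
  expect_identical(sum(a2$is_tf), 10L)

  a3 <- buildGenome(c(X = 50, `2L` = 50), fracSexBiased = 0.4, seed = 2)
  expect_equal(sum(a3$sex_bias_truth == "female"), 20)
  expect_equal(sum(a3$sex_bias_truth == "male"), 20)

  # positions strictly increasing within each arm, ids unique
  for (arm in unique(a3$arm))
    expect_true(all(diff(a3$position[a3$arm == arm]) > 0))
  expect_false(anyDuplicated(a3$gene_id) > 0)

  expect_error(buildGenome(c(X = 0)), "counts")
  expect_error(buildGenome(c(X = 10), fracTF = 1.5), "fractions")
  expect_error(buildGenome(c(Z = 10)), "arms")
})

test_that("karyotypes enforce fly copy-number rules", {
  k <- karyotype("female", "2L")
  expect_identical(unname(k@copies["2L"]), 3L)
  expect_identical(k@label, "trisomy2L_F")
  expect_identical(karyotype("female", "X")@label, "metafemale_F")
  expect_error(new("Karyotype", copies = c(X = 2L), sex = "male",
                   msl2 = FALSE, label = "bad") |> validObject(),
               "male X")
  expect_error(karyotype("female", "5R"), "unknown arm")
  expect_identical(matchedDiploid(k)@label, "diploid_F")
  expect_length(genotypePanel(), 8)
})

test_that("expectedRatio reproduces the theoretical dosage-effect ratios", {
  ann <- buildGenome(c(X = 6, `2L` = 6, `2R` = 6), fracSexBiased = 0,
                     fracResponsive = 1, seed = 1)
  m <- tinyModel(ann)
  dipF <- karyotype("female")
  triF <- karyotype("female", "2L")
  mslF <- karyotype("female", "2L", msl2 = TRUE)
  mslM <- karyotype("male", "2L", msl2 = TRUE)

  r <- expectedRatio(ann, triF, m)
  expect_equal(unname(r[ann$arm == "2L"]), rep(1, 6))       # 3/2 x 2/3
  expect_equal(unname(r[ann$arm == "X"]), rep(2 / 3, 6))
  expect_equal(expectedRatio(ann, dipF, m), rep(1, nrow(ann)))

  r2 <- expectedRatio(ann, mslF, m)
  expect_equal(unname(r2[ann$arm == "X"]), rep(4 / 9, 6))   # 2/3 x 2/3
  expect_equal(unname(r2[ann$arm == "2L"]), rep(2 / 3, 6))

  # males already carry the MSL complex: the transgene factor is 1
  r3 <- expectedRatio(ann, mslM, m, control = karyotype("male", "2L"))
  expect_equal(unname(r3), rep(1, nrow(ann)))

  # metafemale: X genes dosage-compensate, autosomes go to 2/3
  r4 <- expectedRatio(ann, karyotype("female", "X"), m)
  expect_equal(unname(r4[ann$arm == "X"]), rep(1, 6))
  expect_equal(unname(r4[ann$arm == "2R"]), rep(2 / 3, 6))

  # non-responsive genes feel only the cis effect
  ann0 <- buildGenome(c(X = 4, `2L` = 4), fracResponsive = 0, seed = 1)
  m0 <- tinyModel(ann0)
  r5 <- expectedRatio(ann0, triF, m0)
  expect_equal(unname(r5[ann0$arm == "2L"]), rep(3 / 2, 4))
  expect_equal(unname(r5[ann0$arm == "X"]), rep(1, 4))

  expect_error(expectedRatio(ann, triF, m, control = karyotype("male")),
               "same sex")
  annBad <- ann; annBad$arm[1] <- "7Q"
  expect_error(expectedRatio(annBad, triF, m), "unknown arm")
})

test_that("expectedRatio is multiplicative in the single-effect factors", {
  ann <- buildGenome(c(X = 20, `2L` = 20), fracResponsive = 0.5, seed = 9)
  mFull <- tinyModel(ann)
  mCis <- tinyModel(ann, inverseDosage = FALSE)
  triF <- karyotype("female", "2L")
  full <- expectedRatio(ann, triF, mFull)
  cis <- expectedRatio(ann, triF, mCis)
  transOnly <- ifelse(ann$responsive, 2 / 3, 1)
  expect_equal(unname(full), unname(cis * transOnly))
})

test_that("simulateCounts is reproducible and respects degenerate inputs", {
  ann <- buildGenome(c(X = 30, `2L` = 30), seed = 2)
  m <- tinyModel(ann)
  des <- list(simDesign(karyotype("female"), 2))
  ae1 <- simulateCounts(ann, m, des, librarySize = 1e5, seed = 11)
  ae2 <- simulateCounts(ann, m, des, librarySize = 1e5, seed = 11)
  expect_identical(assay(ae1, "counts"), assay(ae2, "counts"))

  m@baselineMean[3] <- 0
  ae3 <- simulateCounts(ann, m, des, librarySize = 1e5, seed = 11)
  expect_true(all(assay(ae3, "counts")[3, ] == 0))

  expect_error(simulateCounts(ann, m, list(), seed = 1), "at least one")
  expect_error(simulateCounts(ann, m, des, librarySize = 0), "positive")
})

test_that("empirical count ratios converge to the analytic oracle", {
  # near-Poisson, 20 replicates: per-gene mean-count ratios approach the
  # expected ratios; composition kept neutral by a small varied arm
  ann <- buildGenome(c(X = 40, `2L` = 30, `2R` = 300, `3L` = 200),
                     fracSexBiased = 0, fracResponsive = 0.1, seed = 4)
  m <- tinyModel(ann)
  m@dispersion[] <- 0
  des <- list(simDesign(karyotype("female"), 20),
              simDesign(karyotype("female", "2L"), 20))
  ae <- simulateCounts(ann, m, des, librarySize = 5e6, seed = 8)
  cts <- assay(ae, "counts")
  ss <- sampleSheet(ae)
  mTri <- rowMeans(cts[, ss$genotype == "trisomy2L_F"])
  mDip <- rowMeans(cts[, ss$genotype == "diploid_F"])
  exp_r <- expectedRatio(ann, karyotype("female", "2L"), m)
  relErr <- abs(mTri / mDip / exp_r - 1)
  expect_lt(median(relErr), 0.01)
  hi <- mDip * 20 >= 1e5   # deeply counted genes: tight convergence
  expect_true(sum(hi) > 10)
  expect_lt(stats::quantile(relErr[hi], 0.95), 0.01)
})

test_that("injected batch shifts appear as between-batch count differences", {
  ann <- buildGenome(c(X = 100, `2L` = 100, `2R` = 100), seed = 3)
  m <- tinyModel(ann, batchLog2Shift = c(b1 = 0, b2 = 0.8))
  des <- list(simDesign(karyotype("female"), 3, batch = "b1"),
              simDesign(karyotype("female"), 3, batch = "b2"))
  ae <- simulateCounts(ann, m, des, librarySize = 5e6, seed = 13)
  cts <- assay(ae, "counts")
  ss <- sampleSheet(ae)
  keep <- rowSums(cts) > 50
  d <- log2(rowMeans(cts[keep, ss$batch == "b2"]) /
              rowMeans(cts[keep, ss$batch == "b1"]))
  expect_lt(abs(mean(d) - 0.8), 0.05)
})

test_that("the experiment container validates and round-trips through TSV", {
  ae <- tinyAE()
  expect_s4_class(ae, "AneuploidyExperiment")
  expect_true(validObject(ae))
  expect_identical(nrow(geneAnnotation(ae)), nrow(ae))
  expect_setequal(colnames(sampleSheet(ae)),
                  c("sample_id", "genotype", "sex", "batch", "replicate",
                    "msl2"))
  dir <- tempfile()
  files <- writeExperimentTSV(ae, dir)
  back <- readExperimentTSV(files["counts"], files["samples"],
                            files["annotation"])
  expect_identical(assay(back, "counts"), assay(ae, "counts"))
  expect_identical(geneAnnotation(back)$arm, geneAnnotation(ae)$arm)

  bad <- assay(ae, "counts"); bad[1, 1] <- -1L
  expect_error(AneuploidyExperiment(bad, rowData(ae),
                                    colData(ae)) |> validObject(),
               "non-negative")
})

test_that("YAML-configured simulation honours genome and design entries", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 3",
    "library_size: 1e5",
    "genome:",
    "  n_genes_per_arm: {X: 20, 2L: 20}",
    "  frac_tf: 0.1",
    "design:",
    "  - {sex: female, replicates: 2}",
    "  - {sex: female, varied_arm: 2L, replicates: 2}"), cfg)
  ae <- simulateFromConfig(cfg)
  expect_identical(dim(ae), c(40L, 4L))
  expect_setequal(unique(sampleSheet(ae)$genotype),
                  c("diploid_F", "trisomy2L_F"))
  expect_identical(sum(geneAnnotation(ae)$is_tf), 4L)
})
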