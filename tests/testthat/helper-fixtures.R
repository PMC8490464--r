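# Shared fixtures, built in code. The small simulated experiment covers the
# six genotypes of the autosomal-aneuploidy design.

tinyGenome <- function(seed = 5L)
  buildGenome(c(X = 150, `2L` = 200, `2R` = 100, `3L` = 50, `3R` = 40,
                `4` = 10), seed = seed)

tinyModel <- function(ann, ...) effectModel(ann, seed = 5L, ...)

panelDesigns <- function(nReps = 3L, batch = "b1") list(
  simDesign(karyotype("female"), nReps, batch),
  simDesign(karyotype("male"), nReps, batch),
  simDesign(karyotype("female", "2L"), nReps, batch),
  simDesign(karyotype("male", "2L"), nReps, batch),
  simDesign(karyotype("female", "2L", msl2 = TRUE), nReps, batch),
  simDesign(karyotype("male", "2L", msl2 = TRUE), nReps, batch))

tinyAE <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ann <- tinyGenome()
      cache <<- simulateCounts(ann, tinyModel(ann), panelDesigns(),
                               librarySize = 5e6, seed = 6L)
    }
    cache
  }
})

# independent brute-force oracles -----------------------------------------

bruteKS <- function(a, b) {
  grid <- sort(c(a, b))
  max(vapply(grid, function(t)
    abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

ksSeriesP <- function(D, na, nb) {
  if (D <= 0) return(1)
  ne <- na * nb / (na + nb)
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  s <- 0
  for (k in 1:200) s <- s + (-1)^(k - 1) * exp(-2 * k^2 * lam^2)
  min(max(2 * s, .Machine$double.xmin), 1)
}

bruteTOM <- function(a) {
  n <- nrow(a)
  a0 <- a; diag(a0) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a0[i, j]
    for (u in seq_len(n))
      if (u != i && u != j) num <- num + a0[i, u] * a0[u, j]
    ki <- sum(a0[i, -i]); kj <- sum(a0[j, -j])
    out[i, j] <- num / (min(ki, kj) + 1 - a0[i, j])
  }
  out
}

bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  run <- Inf
  for (i in n:1) {
    run <- min(run, p[o[i]] * n / i)
    adj[o[i]] <- min(run, 1)
  }
  adj
}

bruteHyper <- function(k, sizeA, sizeB, nU) {
  # P(|A intersect B| >= k) by exhaustive tail summation
  tot <- 0
  for (x in k:min(sizeA, sizeB))
    tot <- tot + choose(sizeA, x) * choose(nU - sizeA, sizeB - x)
  tot / choose(nU, sizeB)
}

# modal-bin containment with inclusive edges: a theoretical value exactly on
# a bin boundary belongs to either adjacent bin
binContains <- function(center, value, width = 0.05)
  value >= center - width / 2 - 1e-9 && value <= center + width / 2 + 1e-9
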