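test_that("freely jointed chain has exact bonds and ideal-chain statistics", {
  n <- 50
  ens <- generateFJC(chainSpec(n, seed = 11), 4000)
  ## all bond lengths equal b
  bl <- apply(ens@coords, 3, function(m) sqrt(rowSums(diff(m)^2)))
  expect_lt(max(abs(bl - B_KUHN)), 1e-9)
  ## mean squared end-to-end = (n-1) b^2 within 3 standard errors
  r2 <- endToEnd(ens)^2
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - (n - 1) * B_KUHN^2), 3 * se)
  ## pure function of the seed
  again <- generateFJC(chainSpec(n, seed = 11), 4000)
  expect_identical(ens@coords, again@coords)
  expect_false(identical(generateFJC(chainSpec(n, seed = 12), 10)@coords,
                         generateFJC(chainSpec(n, seed = 11), 10)@coords))
  expect_error(generateFJC(chainSpec(n), 0), "nFrames")
  expect_error(generateFJC(chainSpec(n, epsilon = -1), 5), "requires")
})

test_that("solvent chain recovers the ideal, swollen and collapsed regimes", {
  ## no interactions: theta-state statistics
  e0 <- generateSolventChain(chainSpec(40, seed = 21), 800)
  expect_equal(fittedNu(e0), 0.5, tolerance = 0.02)
  ## repulsive-only chain swells
  er <- generateSolventChain(chainSpec(40, excludedRadius = 0.4, seed = 22), 600)
  expect_gt(fittedNu(er), 0.55)
  ## strong short-range attraction collapses the chain
  ea <- generateSolventChain(chainSpec(40, excludedRadius = 0.3,
                                       epsilon = -0.4, seed = 23), 600)
  expect_lt(fittedNu(ea), 0.45)
  ## reproducibility
  expect_identical(generateSolventChain(chainSpec(20, seed = 5), 10)@coords,
                   generateSolventChain(chainSpec(20, seed = 5), 10)@coords)
  ## non-positive sweep counts are rejected at spec construction
  expect_error(chainSpec(20, sweepsPerFrame = 0), "sweepsPerFrame")
})

test_that("saved solvent-chain frames are decorrelated at the default spacing", {
  ens <- generateSolventChain(chainSpec(40, seed = 31), 600)
  rg <- radiusOfGyration(ens)
  expect_lt(abs(acf(rg, lag.max = 1, plot = FALSE)$acf[2]), 0.2)
})

test_that("scaling exponent is non-increasing in attraction strength", {
  epsGrid <- c(0, -0.1, -0.2, -0.3, -0.4)
  nus <- vapply(seq_along(epsGrid), function(k) {
    ens <- generateSolventChain(chainSpec(40, excludedRadius = 0.3,
                                          epsilon = epsGrid[k],
                                          seed = 100 + k), 600)
    fittedNu(ens)
  }, numeric(1))
  expect_true(all(diff(nus) < 0))
})

test_that("Gaussian end-to-end sampler matches the analytic density", {
  xi <- 5.44
  d <- sampleGaussianDee(xi, 2e4, seed = 3)
  expect_true(all(d > 0))
  ## mean of the density is 2 xi / sqrt(pi)
  m <- 2 * xi / sqrt(pi)
  v <- xi^2 * (3 / 2 - 4 / pi)  # Maxwell variance with scale xi/sqrt(2)
  expect_lt(abs(mean(d) - m), 3 * sqrt(v / length(d)))
  ## KS distance against the analytic CDF shrinks with n
  cdf <- function(x) {
    a <- xi / sqrt(2)
    pchisq((x / a)^2, df = 3)
  }
  ksBig <- ks.test(d, cdf)$statistic
  ksSmall <- ks.test(sampleGaussianDee(xi, 500, seed = 4), cdf)$statistic
  expect_lt(ksBig, 0.01)
  expect_lt(ksBig, ksSmall)
  expect_identical(sampleGaussianDee(xi, 10, seed = 1),
                   sampleGaussianDee(xi, 10, seed = 1))
  expect_error(sampleGaussianDee(0, 10), "xi")
})

test_that("two-domain generator keeps the domain rigid and the tail ideal", {
  tmpl <- rigidDomainTemplate(30, seed = 2)
  spec <- chainSpec(25, seed = 6)
  td <- generateTwoDomain(25, tmpl, spec, 40)
  expect_equal(nResidues(td), 55)
  top <- topology(td)
  expect_equal(top@residues$domain[1:25], rep("NTD", 25))
  expect_equal(top@residues$domain[26:55], rep("CRD", 30))
  ## intra-domain distances identical across frames
  d1 <- dist(td@coords[26:55, , 1])
  for (f in c(10, 25, 40))
    expect_lt(max(abs(dist(td@coords[26:55, , f]) - d1)), 1e-6)
  ## the tail sub-ensemble reproduces the plain chain's R(s)
  tailTop <- beadTopology(rep("GLY", 25))
  tailEns <- ensemble(tailTop, td@coords[1:25, , , drop = FALSE])
  scTail <- scalingCurve(tailEns, mode = "rms", distance = "backbone")
  ref <- generateSolventChain(chainSpec(25, seed = 99), 400)
  scRef <- scalingCurve(ref, mode = "rms", distance = "backbone")
  ## both are ideal chains: compare to the common closed form b sqrt(s)
  expect_equal(scTail@R, B_KUHN * sqrt(scTail@s), tolerance = 0.08)
  expect_equal(scRef@R, B_KUHN * sqrt(scRef@s), tolerance = 0.08)
  ## the tether holds: tail end sits one bond from the domain's first bead
  gap <- sqrt(colSums((td@coords[25, , ] - td@coords[26, , ])^2))
  expect_equal(unname(gap), rep(B_KUHN, 40), tolerance = 1e-9)
  ## galectin-sized layout inherits the packaged strand table
  tdG <- generateTwoDomain(112, rigidDomainTemplate(138, seed = 1),
                           chainSpec(112, seed = 7), 2)
  expect_length(strands(topology(tdG)), 11)
  expect_error(generateTwoDomain(5, matrix(numeric(0), 0, 3),
                                 chainSpec(5, seed = 1), 2), "tether")
})

test_that("box generator packs molecules beyond tolerance in the box", {
  pool <- generateFJC(chainSpec(8, seed = 3), 60)
  bs <- boxSpec(6, boxEdge = 8, tolerance = 0.4, seed = 14)
  bx <- generateBox(pool, bs, 15)
  expect_equal(nMolecules(bx), 6)
  expect_equal(boxEdges(bx), rep(8, 15))
  nb1 <- beadsPerMolecule(topology(pool))
  for (f in c(1, 8, 15)) {
    xyz <- frameCoords(bx, f)
    for (a in 1:5) for (b in (a + 1):6) {
      da <- xyz[(a - 1) * nb1 + 1:nb1, ]
      db <- xyz[(b - 1) * nb1 + 1:nb1, ]
      dmin <- min(apply(da, 1, function(p) {
        d <- sweep(db, 2, p)
        d <- d - 8 * round(d / 8)
        sqrt(min(rowSums(d^2)))
      }))
      expect_gte(dmin, 0.4)
    }
  }
  ## single molecule: internal distances equal some pool conformation's
  ## (placement is a rigid motion of a drawn conformation)
  one <- generateBox(pool, boxSpec(1, boxEdge = 10, seed = 9), 3)
  d1 <- dist(one@coords[, , 2])
  bestDev <- min(vapply(seq_len(nFrames(pool)), function(f)
    max(abs(dist(pool@coords[, , f]) - d1)), numeric(1)))
  expect_lt(bestDev, 1e-9)
  ## reproducibility
  expect_identical(generateBox(pool, bs, 3)@coords,
                   generateBox(pool, bs, 3)@coords)
  ## impossible packing fails loudly
  expect_error(generateBox(pool, boxSpec(2, boxEdge = 1.2, tolerance = 0.5,
                                         seed = 1), 1, maxAttempts = 5),
               "packing error")
})

test_that("reference SAXS generator applies the affine transform and noise model", {
  q <- seq(0.1, 2, length.out = 50)
  prof <- scatteringProfile(q, 100 * exp(-q^2))
  exact <- generateReferenceSAXS(prof, a = 2, bOffset = 5, noiseLevel = 0,
                                 seed = 1)
  expect_equal(intensities(exact), 2 * intensities(prof) + 5)
  noisy <- generateReferenceSAXS(prof, a = 2, bOffset = 5, noiseLevel = 0.03,
                                 seed = 8)
  expect_equal(sigmas(noisy), 0.03 * abs(2 * intensities(prof)))
  ## chi^2 of the generating model against its own noisy output is about 1
  model <- scatteringProfile(q, 2 * intensities(prof) + 5)
  fit <- chi2Fit(noisy, model)
  expect_lt(abs(fit@chi2 - 1), 3 * sqrt(2 / length(q)))
  expect_identical(intensities(generateReferenceSAXS(prof, seed = 5)),
                   intensities(generateReferenceSAXS(prof, seed = 5)))
  expect_error(generateReferenceSAXS(prof, noiseLevel = -0.1), "noiseLevel")
})
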