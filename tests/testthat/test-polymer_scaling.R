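test_that("scaling curve reproduces rod and ideal-chain closed forms", {
  ## straight rod with 0.38 nm spacing: R(s) = 0.38 s exactly
  top <- beadTopology(rep("GLY", 12))
  rod <- ensembleFromFrames(top, list(cbind(0.38 * (0:11), 0, 0)))
  sc <- scalingCurve(rod, mode = "mean", distance = "backbone")
  expect_equal(sc@R, 0.38 * sc@s, tolerance = 1e-12)

  ## FJC in RMS mode: R(s) = b sqrt(s) within 3 standard errors
  ens <- generateFJC(chainSpec(60, seed = 13), 4000)
  scr <- scalingCurve(ens, mode = "rms", distance = "backbone")
  ## compare at a few separations with a direct per-pair standard error
  for (s in c(5, 20, 40)) {
    d2 <- colSums((ens@coords[1 + s, , ] - ens@coords[1, , ])^2)
    se <- sd(d2) / sqrt(length(d2)) / (2 * B_KUHN * sqrt(s))  # delta method
    expect_lt(abs(scr@R[s] - B_KUHN * sqrt(s)), 5 * se)
  }

  ## arithmetic mean and RMS differ by the Maxwell factor sqrt(8/(3 pi))
  scm <- scalingCurve(ens, mode = "mean", distance = "minbead")
  ratio <- scm@R[30:50] / scr@R[30:50]
  expect_equal(mean(ratio), sqrt(8 / (3 * pi)), tolerance = 0.01)

  expect_error(scalingCurve(ensembleFromFrames(beadTopology(rep("GLY", 2)),
                                               list(matrix(0, 2, 3)))),
               "3 residues")
})

test_that("minimum-bead and backbone distance definitions differ as expected", {
  ## two-bead residues: side-chain beads closer than backbones
  top <- beadTopology(rep("GLY", 3), nBeads = 2, backbone = 1)
  xyz <- rbind(c(0, 0, 0), c(0.4, 0, 0),    # residue 1: BB, SC1
               c(1, 0, 0), c(0.6, 0, 0),    # residue 2: BB, SC1
               c(2, 0, 0), c(1.6, 0, 0))    # residue 3: BB, SC1
  ens <- ensembleFromFrames(top, list(xyz))
  scb <- scalingCurve(ens, mode = "mean", distance = "backbone")
  scm <- scalingCurve(ens, mode = "mean", distance = "minbead")
  expect_equal(scb@R, c(1, 2))
  expect_equal(scm@R, c(0.4, 1.2))
})

test_that("Flory fit is exact on noise-free power-law input", {
  s <- 1:80
  curve <- list(s = s, R = 0.55 * s^0.5)
  fit <- fitFlory(curve, bFixed = NA)
  expect_equal(fit@b, 0.55, tolerance = 1e-6)
  expect_equal(fit@nu, 0.5, tolerance = 1e-6)
  ## identifiability across the physical range of exponents
  for (nu in c(0.33, 0.5, 0.588)) for (b in c(0.38, 0.55)) {
    f <- fitFlory(list(s = s, R = b * s^nu), bFixed = NA)
    expect_equal(f@b, b, tolerance = 1e-6)
    expect_equal(f@nu, nu, tolerance = 1e-6)
  }
  ## fixed-b variant
  ff <- fitFlory(list(s = s, R = 0.55 * s^0.42))
  expect_equal(ff@b, 0.55)
  expect_equal(ff@nu, 0.42, tolerance = 1e-6)
  expect_error(fitFlory(list(s = 1:4, R = (1:4)^0.5), bFixed = NA), ">= 5")
})

test_that("FJC ensembles yield theta-state Flory parameters", {
  ens <- generateFJC(chainSpec(112, seed = 17), 10000)
  fit <- fitFlory(scalingCurve(ens, mode = "rms", distance = "backbone"),
                  bFixed = NA)
  expect_equal(fit@b, B_KUHN, tolerance = 0.02)
  expect_lt(abs(fit@nu - 0.5), 0.02)
})

test_that("theta scan locates the nu = 1/2 crossing", {
  ## exactly linear points crossing at control = 1.04
  control <- seq(1, 1.1, by = 0.01)
  nu <- 0.5 + 1.5 * (control - 1.04)
  ts <- thetaScan(control, nu)
  expect_equal(ts@crossing, 1.04, tolerance = 1e-6)
  ## no crossing when all nu > 1/2
  ts2 <- thetaScan(control, nu + 1)
  expect_true(is.na(ts2@crossing))
  ## decreasing scans work symmetrically
  ts3 <- thetaScan(control, rev(nu))
  expect_equal(ts3@crossing, 1 + 1.1 - 1.04, tolerance = 1e-6)
  ## noisy monotone scan: crossing recovered within one grid spacing
  set.seed(2024)
  nuTrue <- function(l) 0.4 + 0.15 * (l - 1) / 0.1
  lGrid <- seq(1, 1.1, by = 0.01)
  obs <- nuTrue(lGrid) + rnorm(length(lGrid), sd = 0.004)
  tsn <- thetaScan(lGrid, obs)
  trueCross <- 1 + 0.1 / 1.5  # nuTrue = 0.5
  expect_lt(abs(tsn@crossing - trueCross), 0.01)
  expect_error(thetaScan(1:2, c(0.4, 0.6)), ">= 3")
})

test_that("Gaussian-chain density fit recovers xi and flags misfit", {
  ## histogram equal to the analytic density: exact recovery, R^2 = 1
  xi <- 3.7
  mids <- seq(0.1, 4 * xi, length.out = 60)
  fit <- fitGaussianDee(list(mid = mids, density = gaussianDeeDensity(mids, xi)))
  expect_equal(fit@xi, xi, tolerance = 1e-6)
  expect_equal(fit@r2, 1, tolerance = 1e-9)

  ## sampled distances recover the generating xi
  d <- sampleGaussianDee(5.44, 1e5, seed = 20)
  fs <- fitGaussianDee(d)
  expect_equal(fs@xi, 5.44, tolerance = 0.01)
  expect_gt(fs@r2, 0.98)

  ## scale equivariance: scaling the samples scales xi
  f2 <- fitGaussianDee(2.5 * d)
  expect_equal(f2@xi, 2.5 * fs@xi, tolerance = 1e-6)

  ## a well-separated bimodal mixture fits poorly (R^2 < 0.9)
  bim <- c(sampleGaussianDee(1, 5e4, seed = 21),
           sampleGaussianDee(12, 5e4, seed = 22))
  expect_lt(fitGaussianDee(bim)@r2, 0.9)

  expect_error(fitGaussianDee(d[1:50]), ">= 100")
  expect_error(fitGaussianDee(rep(1, 200)), "degenerate")
})
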