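test_that("topology constructor enforces its invariants", {
  top <- beadTopology(c("GLY", "PHE", "ALA"), nBeads = c(1, 2, 1),
                      backbone = 1)
  expect_s4_class(top, "BeadTopology")
  expect_identical(top@residues$aromatic, c(FALSE, TRUE, FALSE))
  expect_equal(beadsPerMolecule(top), 4)

  ## domains must cover the sequence disjointly
  expect_error(beadTopology(rep("GLY", 5),
                            domains = list(A = c(1, 2), B = c(4, 5))),
               "cover")
  expect_error(beadTopology(rep("GLY", 5),
                            domains = list(A = c(1, 3), B = c(3, 5))),
               "disjoint|cover")
  ## strands must stay inside the CRD
  expect_error(beadTopology(rep("GLY", 20),
                            domains = list(NTD = c(1, 10), CRD = c(11, 20)),
                            strands = list(beta1 = c(5, 12))),
               "outside the CRD")
})

test_that("the packaged galectin-3 annotation matches its published layout", {
  top <- readTopology(system.file("extdata", "galectin3_topology.json",
                                  package = "fuzzyens"))
  expect_equal(nResidues(top), 250)
  expect_equal(domains(top)$NTD, c(1L, 112L))
  expect_equal(domains(top)$CRD, c(113L, 250L))
  expect_length(strands(top), 11)
  expect_equal(strands(top)$beta1, c(118L, 121L))
  expect_equal(strands(top)$beta11, c(240L, 249L))
  ## JSON round trip preserves everything
  tf <- withr::local_tempfile(fileext = ".json")
  writeTopology(top, tf)
  top2 <- readTopology(tf)
  expect_equal(top2@residues, top@residues)
  expect_equal(domains(top2), domains(top))
  expect_equal(strands(top2), strands(top))
})

test_that("XYZ round trip preserves coordinates, times and box edges", {
  top <- beadTopology(c("GLY", "PHE", "ALA"), nBeads = c(1, 2, 1))
  set.seed(1)
  frames <- replicate(2, matrix(rnorm(12), ncol = 3), simplify = FALSE)
  ens <- ensembleFromFrames(top, frames, boxEdge = 12.5)
  tf <- withr::local_tempfile(fileext = ".xyz")
  writeEnsemble(ens, tf)
  ens2 <- readEnsemble(tf, top)
  expect_equal(nFrames(ens2), 2)
  expect_lt(max(abs(ens2@coords - ens@coords)), 1e-3)
  expect_equal(boxEdges(ens2), boxEdges(ens))
  expect_equal(frameTimes(ens2), frameTimes(ens))
})

test_that("PDB round trip converts Angstrom to nm and keeps 1e-3 nm fidelity", {
  top <- beadTopology(rep("GLY", 2))
  ## two beads 3.8 Angstrom apart, written in Angstrom on disk
  ens <- ensembleFromFrames(top, list(rbind(c(0, 0, 0), c(0.38, 0, 0)),
                                      rbind(c(0, 0, 0), c(0, 0.38, 0))),
                            boxEdge = 20)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(ens, tf)
  raw <- readLines(tf)
  expect_true(any(grepl("^CRYST1", raw)))
  expect_equal(sum(grepl("^MODEL", raw)), 2)
  ## an ATOM x-coordinate of 3.800 Angstrom appears verbatim
  expect_true(any(grepl("3.800", raw[grepl("^ATOM", raw)], fixed = TRUE)))
  ens2 <- readEnsemble(tf, top)
  d <- sqrt(sum((ens2@coords[2, , 1] - ens2@coords[1, , 1])^2))
  expect_equal(d, 0.38, tolerance = 1e-6)
  expect_lt(max(abs(ens2@coords - ens@coords)), 1e-3)
  expect_equal(boxEdges(ens2)[1], 20)
})

test_that("readers reject malformed input with informative errors", {
  top <- beadTopology(rep("GLY", 3))
  tf <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "frame=1 time=0", "BB 0 0 0", "BB 1 0 0", "BB 2 0 0",
               "BB 3 0 0"), tf)
  expect_error(readEnsemble(tf, top), "frame 1 has 4 beads")
  writeLines(c("3", "frame=1 time=0", "BB 0 0 0", "BB x 0 0", "BB 2 0 0"), tf)
  expect_error(readEnsemble(tf, top), "line 4")
})

test_that("stride keeps the first frame then every k-th", {
  top <- beadTopology(rep("GLY", 2))
  set.seed(2)
  ens <- ensembleFromFrames(top, replicate(20, matrix(rnorm(6), ncol = 3),
                                           simplify = FALSE))
  s5 <- stride(ens, 5)
  expect_equal(nFrames(s5), 4)
  expect_equal(s5@coords[, , 2], ens@coords[, , 6])
  expect_equal(stride(ens, 1)@coords, ens@coords)
  expect_error(stride(ens, 0), "k must be")
  ## composition: stride(stride(E, a), b) == stride(E, a*b)
  for (ab in list(c(2, 5), c(4, 3), c(2, 2))) {
    expect_equal(stride(stride(ens, ab[1]), ab[2])@coords,
                 stride(ens, ab[1] * ab[2])@coords)
  }
  ## ceil(N / k) frame count
  for (k in 1:7) expect_equal(nFrames(stride(ens, k)), ceiling(20 / k))
})

test_that("SAXS curve reader validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.1, 3, length.out = 221)
  prof <- scatteringProfile(q, exp(-q^2), sigma = rep(0.01, 221))
  writeSAXSCurve(prof, tf)
  p2 <- readSAXSCurve(tf)
  expect_length(qValues(p2), 221)
  expect_equal(intensities(p2), intensities(prof), tolerance = 1e-9)
  expect_equal(sigmas(p2), sigmas(prof), tolerance = 1e-9)
  ## empty file
  writeLines(character(), tf)
  expect_error(readSAXSCurve(tf), "format error")
  ## non-monotone q
  writeLines(c("0.2 1 0.1", "0.1 1 0.1"), tf)
  expect_error(readSAXSCurve(tf), "increasing")
  ## non-positive sigma
  writeLines(c("0.1 1 0.1", "0.2 1 0"), tf)
  expect_error(readSAXSCurve(tf), "sigma")
})
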