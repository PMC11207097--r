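test_that("contact rule: 0.7 nm cutoff with three sequence neighbours ignored", {
  top <- beadTopology(rep("GLY", 10))
  place <- function(i, j, d) {
    xyz <- cbind(seq(0, by = 5, length.out = 10), 0, 0)  # all far apart
    xyz[j, ] <- xyz[i, ] + c(d, 0, 0)
    xyz
  }
  ens <- ensembleFromFrames(top, list(place(1, 6, 0.69), place(1, 6, 0.71),
                                      place(2, 5, 0.30)))
  expect_equal(nrow(frameContacts(ens, 1)), 1)    # 0.69 nm, |i-j| = 5
  expect_equal(frameContacts(ens, 1)$j, 6)
  expect_equal(nrow(frameContacts(ens, 2)), 0)    # 0.71 nm: beyond cutoff
  expect_equal(nrow(frameContacts(ens, 3)), 0)    # |i-j| = 3: excluded
})

test_that("frame contacts equal the brute-force bead-pair oracle", {
  set.seed(31)
  top <- beadTopology(sample(c("GLY", "PHE", "SER"), 10, replace = TRUE),
                      nBeads = sample(1:3, 10, replace = TRUE), backbone = 1)
  nb <- beadsPerMolecule(top)
  for (rep in 1:25) {
    xyz <- matrix(runif(nb * 3, 0, 2.5), ncol = 3)
    ens <- ensembleFromFrames(top, list(xyz))
    got <- sortContacts(frameContacts(ens, 1))
    want <- oracleContacts(xyz, top)
    expect_equal(got, want)
  }
})

test_that("inter-molecular contacts follow the minimum-image convention", {
  top <- beadTopology(rep("GLY", 3), nMolecules = 2L)
  L <- 10
  xyz <- rbind(cbind(c(0.0, 0.5, 1.0), 0, 0),
               cbind(c(9.7, 9.2, 8.7), 0, 0))  # near through the boundary
  ens <- ensembleFromFrames(top, list(xyz), boxEdge = L)
  got <- frameContacts(ens, 1, scope = "inter")
  want <- oracleContacts(xyz, top, inter = TRUE, L = L)
  expect_equal(sortContacts(got), want)
  expect_gt(nrow(got), 0)  # wrap-around contact is found
  ## invariance under translation by a lattice vector
  shifted <- xyz
  shifted[4:6, ] <- sweep(shifted[4:6, ], 2, c(L, -L, 2 * L), "+")
  ens2 <- ensembleFromFrames(top, list(shifted), boxEdge = L)
  expect_equal(sortContacts(frameContacts(ens2, 1, scope = "inter")),
               sortContacts(got))
  ## inter scope has no sequence exclusion and needs a box
  noBox <- ensembleFromFrames(top, list(xyz))
  expect_error(frameContacts(noBox, 1, scope = "inter"), "box")
})

test_that("contact probabilities count frames and match the per-frame oracle", {
  top <- beadTopology(rep("GLY", 6))
  near <- cbind(c(0, 3, 6, 9, 12, 0.65), 0, 0)   # residues 1 and 6 in contact
  far <- cbind(c(0, 3, 6, 9, 12, 15), 0, 0)
  frames <- c(replicate(10, near, simplify = FALSE),
              replicate(90, far, simplify = FALSE))
  ens <- ensembleFromFrames(top, frames[sample.int(100)])
  cm <- contactProbabilityMap(ens, "intra")
  expect_equal(cm@probability[1, 6], 0.1)
  expect_equal(cm@probability[6, 1], 0.1)
  expect_equal(sum(cm@probability > 0), 2)
  ## all-far ensemble gives an empty map
  cmEmpty <- contactProbabilityMap(ensembleFromFrames(top, frames[11:30]),
                                   "intra")
  expect_equal(sum(cmEmpty@probability), 0)
  ## exact agreement with aggregating frameContacts over frames
  set.seed(77)
  topR <- beadTopology(rep("GLY", 8))
  framesR <- replicate(40, matrix(runif(24, 0, 1.8), ncol = 3),
                       simplify = FALSE)
  ensR <- ensembleFromFrames(topR, framesR)
  cmR <- contactProbabilityMap(ensR, "intra")
  manual <- matrix(0, 8, 8)
  for (f in 1:40) {
    fc <- frameContacts(ensR, f)
    for (r in seq_len(nrow(fc))) {
      manual[fc$i[r], fc$j[r]] <- manual[fc$i[r], fc$j[r]] + 1
      manual[fc$j[r], fc$i[r]] <- manual[fc$j[r], fc$i[r]] + 1
    }
  }
  expect_equal(cmR@probability, manual / 40)
})

test_that("domain profiles are union events consistent with the pair map", {
  set.seed(41)
  top <- beadTopology(rep("GLY", 20), domains = list(NTD = c(1, 10),
                                                     CRD = c(11, 20)))
  frames <- replicate(60, matrix(runif(60, 0, 2.2), ncol = 3),
                      simplify = FALSE)
  ens <- ensembleFromFrames(top, frames)
  cm <- contactProbabilityMap(ens, "intra")
  dp <- domainProfile(ens, "intra")
  ## union bound: p_i(D) >= max_{j in D} p_ij (exact union event)
  for (i in 1:20) for (d in 1:2) {
    dres <- domainResidues(top, c("NTD", "CRD")[d])
    expect_gte(dp@residueProb[i, d] + 1e-12, max(cm@probability[i, dres]))
  }
  ## residue touching a domain in every frame has probability 1
  touch <- lapply(1:3, function(f) {
    xyz <- cbind(seq(0, by = 4, length.out = 20), 0, 0)
    xyz[15, ] <- xyz[2, ] + c(0.3, 0, 0)   # residue 15 touches NTD always
    xyz
  })
  dpT <- domainProfile(ensembleFromFrames(top, touch), "intra")
  expect_equal(unname(dpT@residueProb[15, "NTD"]), 1)
})

test_that("inter-domain probabilities match hand counts on a 3-frame toy", {
  top <- beadTopology(rep("GLY", 4), domains = list(NTD = c(1, 2),
                                                    CRD = c(3, 4)),
                      nMolecules = 2L)
  L <- 20
  apart <- rbind(cbind(c(0, 0.5, 1, 1.5), 0, 0),
                 cbind(c(0, 0.5, 1, 1.5), 10, 0))
  touching <- apart
  touching[5, ] <- c(0, 0.5, 0)   # mol2 residue 1 near mol1 residue 1 (NTD-NTD)
  ens <- ensembleFromFrames(top, list(apart, touching, apart), boxEdge = L)
  dp <- domainProfile(ens, "inter")
  expect_equal(dp@domainProb["NTD", "NTD"], 1 / 3)
  expect_equal(dp@domainProb["NTD", "CRD"], 0)
  expect_equal(dp@domainProb["CRD", "CRD"], 0)
  ## two molecules never within cutoff: all zeros
  dp0 <- domainProfile(ensembleFromFrames(top, list(apart), boxEdge = L),
                       "inter")
  expect_true(all(dp0@domainProb == 0))
  ## strand probability is an union over its residues' events
  topS <- beadTopology(rep("GLY", 8),
                       domains = list(NTD = c(1, 4), CRD = c(5, 8)),
                       strands = list(beta1 = c(5, 6)))
  xyzS <- cbind(seq(0, by = 4, length.out = 8), 0, 0)
  xyzS[5, ] <- xyzS[1, ] + c(0.4, 0, 0)
  dpS <- domainProfile(ensembleFromFrames(topS, list(xyzS)), "intra")
  expect_gte(dpS@strandProb["beta1", "NTD"],
             max(dpS@residueProb[5:6, "NTD"]))
  expect_equal(dpS@strandProb["beta1", "NTD"], 1)
})

test_that("map comparison flags engineered differences and nothing else", {
  top <- beadTopology(rep("GLY", 8))
  mkEns <- function(pContact) {
    ## residues 1 and 6 in contact in a fixed fraction of frames,
    ## spread evenly so every block sees the same frequency
    frames <- lapply(1:100, function(f) {
      xyz <- cbind(seq(0, by = 5, length.out = 8), 0, 0)
      if ((f %% 10) < 10 * pContact) xyz[6, ] <- xyz[1, ] + c(0.5, 0, 0)
      xyz
    })
    ensembleFromFrames(top, frames)
  }
  mA <- contactProbabilityMap(mkEns(0.5), "intra")
  mB <- contactProbabilityMap(mkEns(0.7), "intra")
  cmp <- compareMaps(mA, mB)
  expect_equal(cmp@delta[1, 6], 0.2, tolerance = 1e-12)
  expect_true(cmp@masks[["0.005"]][1, 6])
  ## a map compared with itself is everywhere insignificant
  self <- compareMaps(mA, mA)
  expect_equal(sum(vapply(self@masks, sum, numeric(1))), 0)
  ## masks are nested: mask(0.005) within mask(0.01) within mask(0.05)
  expect_true(all(cmp@masks[["0.01"]] >= cmp@masks[["0.005"]]))
  expect_true(all(cmp@masks[["0.05"]] >= cmp@masks[["0.01"]]))
  expect_error(compareMaps(mA, contactProbabilityMap(mkEns(0.5), "intra",
                                                     nBlocks = 1L)),
               ">= 2 blocks")
})
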