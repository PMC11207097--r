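#' Chain specification for the synthetic generators
#'
#' @param nResidues number of residues (one bead per residue).
#' @param bondLength bond length, nm. The default 0.55 nm is the Kuhn length
#'   commonly adopted for intrinsically disordered proteins.
#' @param excludedRadius hard-core radius, nm; 0 disables excluded volume.
#' @param epsilon pair-well depth in kT: negative values add a short-range
#'   attraction (poor solvent), non-negative values leave only the repulsive
#'   core (good solvent). This is the generator's solvent-quality knob.
#' @param wellWidth width of the square well beyond the core, nm.
#' @param sweepsPerFrame Monte Carlo sweeps between saved frames.
#' @param seed integer RNG seed.
#' @return a [ChainSpec].
#' @export
chainSpec <- function(nResidues, bondLength = 0.55, excludedRadius = 0,
                      epsilon = 0, wellWidth = 0.3, sweepsPerFrame = 60L,
                      seed = 1L) {
  new("ChainSpec", nResidues = as.integer(nResidues),
      bondLength = bondLength, excludedRadius = excludedRadius,
      epsilon = epsilon, wellWidth = wellWidth,
      sweepsPerFrame = as.integer(sweepsPerFrame), seed = as.integer(seed))
}

#' Box specification for multi-molecule ensembles
#'
#' @param nMolecules number of molecules to place.
#' @param boxEdge cubic box edge, nm (default 20 nm).
#' @param tolerance minimum accepted inter-molecular bead distance during
#'   placement, nm (default 0.4 nm).
#' @param seed integer RNG seed.
#' @return a [BoxSpec].
#' @export
boxSpec <- function(nMolecules, boxEdge = 20, tolerance = 0.4, seed = 1L) {
  new("BoxSpec", boxEdge = boxEdge, nMolecules = as.integer(nMolecules),
      tolerance = tolerance, seed = as.integer(seed))
}

chainTopology <- function(n, domains = NULL, strands = list(), nMolecules = 1L)
  beadTopology(rep("GLY", n), domains = domains, strands = strands,
               nMolecules = nMolecules)

## nFrames x 3 matrix of uniformly random unit vectors
randomUnitVectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## uniform random rotation matrix (quaternion method)
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a freely jointed chain ensemble
#'
#' Exact sampler of the ideal chain: one bead per residue, every bond an
#' independent uniformly random direction of length `bondLength`. Frames are
#' i.i.d.; requires `excludedRadius = 0` and `epsilon = 0`.
#'
#' @param spec a [ChainSpec] with no interactions.
#' @param nFrames number of frames (>= 1).
#' @return an [Ensemble].
#' @examples
#' ens <- generateFJC(chainSpec(20, seed = 7), 100)
#' nFrames(ens)
#' @export
generateFJC <- function(spec, nFrames) {
  stopifnot(is(spec, "ChainSpec"))
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (spec@excludedRadius != 0 || spec@epsilon != 0)
    stop("generateFJC requires excludedRadius = 0 and epsilon = 0")
  n <- spec@nResidues
  b <- spec@bondLength
  coords <- withr::with_seed(spec@seed, {
    bonds <- randomUnitVectors((n - 1L) * nFrames) * b
    ## cumulative sums per frame and component: [n-1, nFrames] blocks
    arr <- array(0, c(n, 3, nFrames))
    for (d in 1:3) {
      m <- matrix(bonds[, d], nrow = n - 1L)
      arr[2:n, d, ] <- apply(m, 2, cumsum)
    }
    arr
  })
  ensemble(chainTopology(n), coords)
}

#' Generate a bead-spring chain ensemble by Metropolis Monte Carlo
#'
#' Stiff harmonic bonds at the spec bond length, a hard core of radius
#' `excludedRadius` and, for `epsilon < 0`, a square well of depth
#' `|epsilon|` over `[excludedRadius, excludedRadius + wellWidth)` between
#' all bead pairs separated by two or more bonds. Single-bead displacement
#' and crankshaft moves; `sweepsPerFrame` sweeps between saved frames and a
#' burn-in before the first. Tuning `epsilon` moves the chain through poor,
#' theta and good solvent regimes (scaling exponent roughly 0.4-0.6).
#'
#' @param spec a [ChainSpec] (`nResidues >= 10`).
#' @param nFrames number of frames to save.
#' @param burninSweeps equilibration sweeps before the first saved frame.
#' @return an [Ensemble].
#' @export
generateSolventChain <- function(spec, nFrames, burninSweeps = 2000L) {
  stopifnot(is(spec, "ChainSpec"))
  if (spec@nResidues < 10) stop("generateSolventChain requires nResidues >= 10")
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (spec@sweepsPerFrame < 1) stop("sweepsPerFrame must be >= 1")
  b <- spec@bondLength
  coords <- cpp_mc_chain(spec@nResidues, b, spec@excludedRadius, spec@epsilon,
                         spec@wellWidth, 200 / b^2, as.integer(nFrames),
                         spec@sweepsPerFrame, as.integer(burninSweeps),
                         0.35 * b, spec@seed)
  ensemble(chainTopology(spec@nResidues), coords)
}

#' Sample Gaussian-chain end-to-end distances
#'
#' Draws from p(d) = 4 d^2 exp[-(d/xi)^2] / (sqrt(pi) xi^3), implemented as
#' the norm of a 3-vector of independent zero-mean Gaussians with standard
#' deviation xi/sqrt(2) (exact, no rejection). The mean of the density is
#' 2 xi / sqrt(pi).
#'
#' @param xi scale parameter, nm (> 0).
#' @param n number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return numeric vector of distances, nm.
#' @export
sampleGaussianDee <- function(xi, n, seed = 1L) {
  if (xi <= 0) stop("xi must be positive")
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(as.integer(seed), {
    m <- matrix(stats::rnorm(3 * n, sd = xi / sqrt(2)), ncol = 3)
    sqrt(rowSums(m^2))
  })
}

#' Analytic Gaussian-chain end-to-end distance density
#' @param d distances, nm.
#' @param xi scale parameter, nm.
#' @export
gaussianDeeDensity <- function(d, xi)
  4 * d^2 * exp(-(d / xi)^2) / (sqrt(pi) * xi^3)

#' Generate a two-domain ensemble: rigid domain with a flexible tail
#'
#' Emulates the architecture of a mixed-folded protein such as galectin-3:
#' an intrinsically disordered N-terminal tail (residues `1..tailResidues`,
#' domain label `"NTD"`) tethered to a rigid domain (label `"CRD"`). Per
#' frame the domain template is copied with a random rigid-body orientation
#' about its tether bead (its first residue), and a tail conformation drawn
#' from the bead-spring chain of [generateSolventChain()] is attached so
#' that its C-terminal bead sits one bond length from the tether. The tail
#' is a phantom with respect to the domain: its internal statistics match
#' the plain solvent chain by construction.
#'
#' @param tailResidues number of tail residues.
#' @param domainTemplate numeric matrix `[k, 3]` of rigid domain bead
#'   coordinates (one bead per residue), nm.
#' @param spec a [ChainSpec] for the tail (its `nResidues` is ignored).
#' @param nFrames number of frames.
#' @param strands named list of beta-strand residue intervals on the full
#'   1-based numbering (tail first, then domain). Defaults to the packaged
#'   galectin-3 table when the sizes match (112 + 138 residues), otherwise
#'   empty.
#' @return an [Ensemble] with domains `NTD` and `CRD`.
#' @export
generateTwoDomain <- function(tailResidues, domainTemplate, spec, nFrames,
                              strands = NULL) {
  if (is.null(dim(domainTemplate)) || ncol(domainTemplate) != 3)
    stop("argument error: domainTemplate must be a [k, 3] coordinate matrix")
  k <- nrow(domainTemplate)
  if (k < 1) stop("argument error: tether bead missing (empty domain template)")
  nt <- as.integer(tailResidues)
  n <- nt + k
  if (is.null(strands)) {
    strands <- if (nt == 112L && k == 138L) galectin3Domains()$strands else list()
  }
  top <- chainTopology(n, domains = list(NTD = c(1L, nt), CRD = c(nt + 1L, n)),
                       strands = strands)
  tailSpec <- spec
  tailSpec@nResidues <- nt
  tail <- generateSolventChain(tailSpec, nFrames)
  tether <- domainTemplate[1, ]
  dom0 <- sweep(domainTemplate, 2, tether)  # tether at origin
  b <- spec@bondLength
  coords <- withr::with_seed(spec@seed + 1L, {
    arr <- array(0, c(n, 3, nFrames))
    for (f in seq_len(nFrames)) {
      R <- randomRotation()
      dom <- dom0 %*% t(R)
      u <- randomUnitVectors(1)
      tl <- tail@coords[, , f]
      ## attach tail: its last residue one bond from the tether bead
      shift <- as.numeric(u * b) - tl[nt, ]
      arr[seq_len(nt), , f] <- sweep(tl, 2, shift, "+")
      arr[nt + seq_len(k), , f] <- dom
    }
    arr
  })
  ensemble(top, coords)
}

#' Compact rigid-domain template
#'
#' Deterministic (seeded) blob of beads with a minimum separation,
#' emulating a folded domain of the given size; used as the
#' `domainTemplate` of [generateTwoDomain()].
#'
#' @param nResidues beads in the domain (default 138, a CRD-sized domain).
#' @param minSeparation minimum bead separation, nm.
#' @param seed integer RNG seed.
#' @return numeric matrix `[nResidues, 3]`, nm.
#' @export
rigidDomainTemplate <- function(nResidues = 138L, minSeparation = 0.45,
                                seed = 1L) {
  ## beads on a jittered cubic lattice: compact and clash-free
  withr::with_seed(as.integer(seed), {
    a <- minSeparation * 1.25
    side <- ceiling(nResidues^(1 / 3))
    g <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side))) * a
    g <- g[seq_len(nResidues), , drop = FALSE]
    g + matrix(stats::runif(3 * nResidues, -0.08, 0.08) * minSeparation,
               ncol = 3)
  })
}

#' Place molecules in a periodic cubic box
#'
#' Draws a conformation for each molecule from `molecules` (uniformly at
#' random over its frames), applies a random rotation, and places the
#' molecule at a random position in the box, rejecting placements in which
#' any inter-molecular bead distance (minimum-image convention) falls below
#' the tolerance. Molecule centers are wrapped into the box; molecules stay
#' whole.
#'
#' @param molecules an [Ensemble] of single-molecule conformations to draw
#'   from.
#' @param box a [BoxSpec].
#' @param nFrames number of frames to build.
#' @param maxAttempts placement attempts per molecule before a packing error.
#' @return an [Ensemble] whose topology replicates the molecule
#'   `box@nMolecules` times.
#' @export
generateBox <- function(molecules, box, nFrames, maxAttempts = 200L) {
  stopifnot(is(molecules, "Ensemble"), is(box, "BoxSpec"))
  if (nMolecules(molecules) != 1L)
    stop("argument error: 'molecules' must be a single-molecule ensemble")
  top1 <- topology(molecules)
  nm <- box@nMolecules
  L <- box@boxEdge
  nb1 <- beadsPerMolecule(top1)
  top <- beadTopology(top1@residues$name, nBeads = top1@residues$nBeads,
                      backbone = top1@residues$backbone,
                      domains = top1@domains, strands = top1@strands,
                      nMolecules = nm)
  nfPool <- nFrames(molecules)
  coords <- withr::with_seed(box@seed, {
    arr <- array(0, c(nb1 * nm, 3, nFrames))
    for (f in seq_len(nFrames)) {
      placed <- list()
      for (m in seq_len(nm)) {
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          conf <- molecules@coords[, , sample.int(nfPool, 1)]
          if (is.null(dim(conf))) conf <- matrix(conf, ncol = 3)
          ctr <- colMeans(conf)
          conf <- sweep(conf, 2, ctr) %*% t(randomRotation())
          if (2 * max(abs(conf)) >= L) next  # conformation larger than the box
          pos <- stats::runif(3, 0, L)
          conf <- sweep(conf, 2, pos, "+")
          clash <- FALSE
          for (p in placed) {
            if (cpp_min_cross_dist(conf, p, L) < box@tolerance) {
              clash <- TRUE
              break
            }
          }
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf("packing error: molecule %d of frame %d could not be placed after %d attempts",
                       m, f, maxAttempts))
        placed[[m]] <- conf
        arr[(m - 1L) * nb1 + seq_len(nb1), , f] <- conf
      }
    }
    arr
  })
  ensemble(top, coords, boxEdge = L)
}

#' Generate a noisy reference scattering curve
#'
#' Returns `a * I(q) + bOffset` plus Gaussian noise with standard deviation
#' `noiseLevel * |a * I(q)|`; the profile's uncertainties are set to that
#' standard deviation. A synthetic stand-in for an experimental SAXS
#' dataset.
#'
#' @param profile a [ScatteringProfile] (its uncertainties are ignored).
#' @param a scale factor.
#' @param bOffset additive offset.
#' @param noiseLevel relative noise level (>= 0).
#' @param seed integer RNG seed.
#' @return a [ScatteringProfile] with uncertainties.
#' @export
generateReferenceSAXS <- function(profile, a = 1, bOffset = 0,
                                  noiseLevel = 0.01, seed = 1L) {
  stopifnot(is(profile, "ScatteringProfile"))
  if (noiseLevel < 0) stop("noiseLevel must be >= 0")
  base <- a * profile@intensity + bOffset
  sd <- noiseLevel * abs(a * profile@intensity)
  I <- withr::with_seed(as.integer(seed),
                        base + stats::rnorm(length(base), sd = sd))
  scatteringProfile(profile@q, I,
                    sigma = if (all(sd > 0)) sd else pmax(sd, 1e-12))
}
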