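#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fuzzyens, .registration = TRUE
NULL

AROMATIC_NAMES <- c("PHE", "TRP", "TYR")

#' Bead topology of one or more identical coarse-grained molecules
#'
#' Describes the residue/bead layout of a coarse-grained protein model:
#' ordered residues (1-based sequence positions), the number of beads per
#' residue with one designated backbone bead, aromatic flags (set for
#' PHE/TRP/TYR), domain ranges (inclusive residue intervals, disjoint and
#' covering the sequence) and beta-strand ranges. A topology may describe
#' several identical molecules (positional identity).
#'
#' @slot residues data.frame with one row per residue of one molecule:
#'   `index` (1-based sequence position), `name` (3-letter code), `nBeads`,
#'   `backbone` (bead number within the residue), `aromatic`, `domain`.
#' @slot domains named list of inclusive residue intervals `c(first, last)`.
#' @slot strands named list of inclusive residue intervals (beta strands).
#' @slot nMolecules number of identical copies of the molecule.
#' @exportClass BeadTopology
setClass("BeadTopology",
  representation(residues = "data.frame", domains = "list",
                 strands = "list", nMolecules = "integer"))

setValidity("BeadTopology", function(object) {
  r <- object@residues
  msgs <- character()
  need <- c("index", "name", "nBeads", "backbone", "aromatic", "domain")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  n <- nrow(r)
  if (n < 1) msgs <- c(msgs, "topology needs at least one residue")
  if (!identical(r$index, seq_len(n)))
    msgs <- c(msgs, "residue indices must be 1..n_residues in order")
  if (any(r$nBeads < 1)) msgs <- c(msgs, "every residue needs >= 1 bead")
  if (any(r$backbone < 1 | r$backbone > r$nBeads))
    msgs <- c(msgs, "each residue needs exactly one backbone bead within 1..nBeads")
  if (!identical(r$aromatic, toupper(r$name) %in% AROMATIC_NAMES))
    msgs <- c(msgs, "aromatic flag must be TRUE iff residue name is PHE, TRP or TYR")
  ## domains: disjoint, covering 1..n
  cov <- integer(n)
  for (d in names(object@domains)) {
    iv <- object@domains[[d]]
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 1 || iv[2] > n) {
      msgs <- c(msgs, sprintf("domain '%s' has an invalid interval", d))
      next
    }
    cov[iv[1]:iv[2]] <- cov[iv[1]:iv[2]] + 1L
  }
  if (length(object@domains) && any(cov != 1L))
    msgs <- c(msgs, "domain ranges must be disjoint and cover 1..n_residues")
  ## strands: inside the CRD domain if one is declared, inside the sequence anyway
  crd <- object@domains[["CRD"]]
  for (s in names(object@strands)) {
    iv <- object@strands[[s]]
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 1 || iv[2] > n)
      msgs <- c(msgs, sprintf("strand '%s' has an invalid interval", s))
    else if (!is.null(crd) && (iv[1] < crd[1] || iv[2] > crd[2]))
      msgs <- c(msgs, sprintf("strand '%s' lies outside the CRD range", s))
  }
  if (length(object@nMolecules) != 1 || object@nMolecules < 1)
    msgs <- c(msgs, "nMolecules must be a single count >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Conformational ensemble of coarse-grained frames
#'
#' Ordered conformation frames over a [BeadTopology]. Coordinates are stored
#' in nanometres as an array `[n_beads_total, 3, n_frames]` with molecules
#' concatenated in a fixed order. Each frame carries a time stamp (ns) and an
#' optional cubic box edge (nm; `NA` for single-molecule analyses).
#'
#' @slot topology a [BeadTopology].
#' @slot coords numeric array `[beads, 3, frames]`, nm.
#' @slot time numeric vector of frame times, ns.
#' @slot boxEdge numeric vector of cubic box edges per frame, nm (or `NA`).
#' @exportClass Ensemble
setClass("Ensemble",
  representation(topology = "BeadTopology", coords = "array",
                 time = "numeric", boxEdge = "numeric"))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  msgs <- character()
  nbExp <- beadsPerMolecule(object@topology) * object@topology@nMolecules
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an array [beads, 3, frames]")
  if (d[1] != nbExp)
    msgs <- c(msgs, sprintf("bead count %d does not match topology (%d)", d[1], nbExp))
  if (d[3] < 1) msgs <- c(msgs, "ensemble needs at least one frame")
  if (length(object@time) != d[3]) msgs <- c(msgs, "time must have one entry per frame")
  if (length(object@boxEdge) != d[3]) msgs <- c(msgs, "boxEdge must have one entry per frame")
  if (any(!is.na(object@boxEdge) & object@boxEdge <= 0))
    msgs <- c(msgs, "box edge must be positive when present")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Scattering intensity profile I(q)
#'
#' @slot q momentum transfer grid, nm^-1, strictly increasing.
#' @slot intensity I(q), arbitrary units.
#' @slot sigma per-point uncertainties (length 0 when absent).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric"))

setValidity("ScatteringProfile", function(object) {
  msgs <- character()
  n <- length(object@q)
  if (n < 1) msgs <- c(msgs, "profile needs at least one point")
  if (n > 1 && any(diff(object@q) <= 0)) msgs <- c(msgs, "q must be strictly increasing")
  if (length(object@intensity) != n) msgs <- c(msgs, "intensity length must match q")
  if (length(object@sigma) && length(object@sigma) != n)
    msgs <- c(msgs, "sigma length must match q (or be empty)")
  if (length(object@sigma) && any(object@sigma <= 0))
    msgs <- c(msgs, "sigma must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Residue-pair contact probability map
#'
#' Symmetric matrix of contact probabilities p_ij (contact-frame count over
#' total frames), with per-pair block errors and the per-block frequencies
#' used for significance testing. `scope` is `"intra"` (within-molecule
#' contacts, near-diagonal pairs excluded) or `"inter"` (across molecules
#' under the minimum-image convention).
#'
#' @slot probability symmetric matrix of p_ij in [0,1].
#' @slot error per-pair block-error estimates.
#' @slot blockMeans array `[res, res, blocks]` of per-block contact frequencies.
#' @slot eligible logical matrix of pairs included in the analysis.
#' @slot scope `"intra"` or `"inter"`.
#' @slot nFrames,cutoff,nNeighborsIgnored analysis parameters.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(probability = "matrix", error = "matrix",
                 blockMeans = "array", eligible = "matrix",
                 scope = "character", nFrames = "integer",
                 cutoff = "numeric", nNeighborsIgnored = "integer"))

setValidity("ContactMap", function(object) {
  p <- object@probability
  msgs <- character()
  if (nrow(p) != ncol(p)) msgs <- c(msgs, "probability matrix must be square")
  if (any(p < 0 | p > 1)) msgs <- c(msgs, "probabilities must lie in [0,1]")
  if (max(abs(p - t(p))) > 1e-12) msgs <- c(msgs, "probability matrix must be symmetric")
  if (!object@scope %in% c("intra", "inter")) msgs <- c(msgs, "scope must be intra or inter")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Residue-vs-domain and strand-vs-domain contact probabilities
#'
#' For intra scope, `residueProb[i, D]` is the fraction of frames in which
#' residue i contacts at least one residue of domain D within the same
#' molecule (union event). For inter scope the contacted domain belongs to a
#' different molecule, and `domainProb[D1, D2]` is the fraction of frames
#' with at least one D1-D2 cross-molecule contact.
#'
#' @slot residueProb matrix `[residues, domains]`.
#' @slot residueErr block errors for `residueProb`.
#' @slot strandProb matrix `[strands, domains]`.
#' @slot strandErr block errors for `strandProb`.
#' @slot domainProb matrix `[domains, domains]` (inter scope; empty for intra).
#' @slot domainErr block errors for `domainProb`.
#' @slot scope `"intra"` or `"inter"`.
#' @exportClass DomainContactProfile
setClass("DomainContactProfile",
  representation(residueProb = "matrix", residueErr = "matrix",
                 strandProb = "matrix", strandErr = "matrix",
                 domainProb = "matrix", domainErr = "matrix",
                 scope = "character"))

setValidity("DomainContactProfile", function(object) {
  vals <- c(object@residueProb, object@strandProb, object@domainProb)
  if (length(vals) && any(vals < -1e-12 | vals > 1 + 1e-12))
    return("all probabilities must lie in [0,1]")
  TRUE
})

#' Comparison of two contact maps with per-pair ANOVA significance
#'
#' @slot delta matrix of |p_A - p_B|.
#' @slot pValue per-pair one-way ANOVA p-values on block means.
#' @slot masks named list of logical matrices, one per threshold; a pair is
#'   masked when its p-value is below the threshold and |delta| exceeds
#'   `minDelta`. Masks are nested across thresholds.
#' @slot thresholds,minDelta the comparison parameters.
#' @exportClass MapComparison
setClass("MapComparison",
  representation(delta = "matrix", pValue = "matrix", masks = "list",
                 thresholds = "numeric", minDelta = "numeric"))

#' Flory scaling-exponent fit R(s) = b s^nu
#'
#' @slot b Kuhn length, nm (fixed or fitted).
#' @slot nu Flory scaling exponent.
#' @slot bFixed was b held fixed?
#' @slot residual root-mean-square fit residual, nm.
#' @slot sMin smallest sequence separation used.
#' @exportClass FloryFit
setClass("FloryFit",
  representation(b = "numeric", nu = "numeric", bFixed = "logical",
                 residual = "numeric", sMin = "numeric"))

setValidity("FloryFit", function(object) {
  if (object@nu <= 0 || object@nu >= 1) "nu must lie in (0,1)" else TRUE
})

#' Inter-residue distance scaling curve R(s)
#'
#' @slot s sequence separations (>= 1).
#' @slot R mean inter-residue distance per separation, nm.
#' @slot mode `"mean"` (arithmetic) or `"rms"`.
#' @slot distance `"minbead"` or `"backbone"`.
#' @slot domain domain label the curve was computed over.
#' @exportClass ScalingCurve
setClass("ScalingCurve",
  representation(s = "numeric", R = "numeric", mode = "character",
                 distance = "character", domain = "character"))

setValidity("ScalingCurve", function(object) {
  msgs <- character()
  if (any(object@s < 1)) msgs <- c(msgs, "separations must be >= 1")
  if (any(object@R <= 0)) msgs <- c(msgs, "distances must be positive")
  if (length(object@s) != length(object@R)) msgs <- c(msgs, "s and R must align")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Theta-point scan of the scaling exponent against a solvent-quality control
#'
#' @slot control scan control values (e.g. an interaction rescaling factor).
#' @slot nu fitted scaling exponents at the scan points.
#' @slot crossing control value at which the smoothed nu(control) curve
#'   crosses 1/2 (the theta point), or `NA` if 1/2 is not bracketed.
#' @slot grid data.frame of the smoothed curve on a fine control grid.
#' @exportClass ThetaScan
setClass("ThetaScan",
  representation(control = "numeric", nu = "numeric", crossing = "numeric",
                 grid = "data.frame"))

#' Gaussian-chain end-to-end distance distribution fit
#'
#' Least-squares fit of p(d) = 4 d^2 exp[-(d/xi)^2] / (sqrt(pi) xi^3) to a
#' normalized histogram of end-to-end distances.
#'
#' @slot xi fitted scale parameter, nm.
#' @slot r2 squared Pearson correlation between histogram densities and
#'   fitted densities at the bin centres.
#' @slot binCenters,density,fitted the histogram and the fitted curve.
#' @exportClass GaussianChainFit
setClass("GaussianChainFit",
  representation(xi = "numeric", r2 = "numeric", binCenters = "numeric",
                 density = "numeric", fitted = "numeric"))

setValidity("GaussianChainFit", function(object) {
  msgs <- character()
  if (object@xi <= 0) msgs <- c(msgs, "xi must be positive")
  if (object@r2 < -1 || object@r2 > 1) msgs <- c(msgs, "R^2 must lie in [-1,1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Chi-square scale/offset fit of a model scattering profile to a reference
#'
#' chi^2(a,b) = (1/n) sum_i (I_ref(q_i) - a I_model(q_i) - b)^2 / sigma_i^2,
#' minimized in closed form over scale a and offset b.
#'
#' @slot a fitted scale.
#' @slot bOffset fitted offset.
#' @slot chi2 minimized chi-square (1/n normalization).
#' @slot n number of reference points.
#' @exportClass Chi2Fit
setClass("Chi2Fit",
  representation(a = "numeric", bOffset = "numeric", chi2 = "numeric",
                 n = "integer"))

setValidity("Chi2Fit", function(object) {
  if (object@chi2 < 0) "chi2 must be non-negative" else TRUE
})

#' Summary of a correlated observable time series
#'
#' @slot mean arithmetic frame mean.
#' @slot blockError block-error plateau (standard error at the largest block
#'   size by default).
#' @slot blockTable data.frame of block size vs standard error of block means.
#' @slot histogram data.frame `mid`, `density` (normalized: sums to 1 after
#'   multiplication by the bin width), plus `lower`/`upper` bin edges.
#' @exportClass SeriesSummary
setClass("SeriesSummary",
  representation(mean = "numeric", blockError = "numeric",
                 blockTable = "data.frame", histogram = "data.frame"))

#' Per-frame oligomer cluster statistics
#'
#' @slot nClusters number of clusters per frame.
#' @slot largestCluster size of the largest cluster per frame.
#' @slot histNClusters,histLargest normalized histograms over 1..n_molecules.
#' @slot partitions list of per-frame partitions (integer cluster labels per
#'   molecule).
#' @exportClass ClusterSeries
setClass("ClusterSeries",
  representation(nClusters = "integer", largestCluster = "integer",
                 histNClusters = "numeric", histLargest = "numeric",
                 partitions = "list"))

setValidity("ClusterSeries", function(object) {
  msgs <- character()
  if (abs(sum(object@histNClusters) - 1) > 1e-9)
    msgs <- c(msgs, "cluster-count histogram must sum to 1")
  if (abs(sum(object@histLargest) - 1) > 1e-9)
    msgs <- c(msgs, "largest-cluster histogram must sum to 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Specification of a synthetic bead-spring chain
#'
#' @slot nResidues number of residues (one bead each).
#' @slot bondLength bond length b, nm (Kuhn length; default 0.55 nm).
#' @slot excludedRadius hard-core radius, nm (0 disables excluded volume).
#' @slot epsilon pair-well depth, kT; negative values are attractive
#'   (solvent-quality knob), non-negative values leave only the repulsive core.
#' @slot wellWidth width of the square well beyond the core, nm.
#' @slot sweepsPerFrame Monte Carlo sweeps between saved frames.
#' @slot seed RNG seed; every generator is a pure function of it.
#' @exportClass ChainSpec
setClass("ChainSpec",
  representation(nResidues = "integer", bondLength = "numeric",
                 excludedRadius = "numeric", epsilon = "numeric",
                 wellWidth = "numeric", sweepsPerFrame = "integer",
                 seed = "integer"))

setValidity("ChainSpec", function(object) {
  msgs <- character()
  if (object@nResidues < 2) msgs <- c(msgs, "nResidues must be >= 2")
  if (object@bondLength <= 0) msgs <- c(msgs, "bondLength must be positive")
  if (object@excludedRadius < 0) msgs <- c(msgs, "excludedRadius must be >= 0")
  if (object@sweepsPerFrame < 1) msgs <- c(msgs, "sweepsPerFrame must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Specification of a periodic multi-molecule box
#'
#' @slot boxEdge cubic box edge L, nm.
#' @slot nMolecules number of molecules to place.
#' @slot tolerance minimum inter-molecular bead separation accepted during
#'   placement, nm.
#' @slot seed RNG seed.
#' @exportClass BoxSpec
setClass("BoxSpec",
  representation(boxEdge = "numeric", nMolecules = "integer",
                 tolerance = "numeric", seed = "integer"))

setValidity("BoxSpec", function(object) {
  msgs <- character()
  if (object@boxEdge <= 0) msgs <- c(msgs, "boxEdge must be positive")
  if (object@nMolecules < 1) msgs <- c(msgs, "nMolecules must be >= 1")
  if (object@tolerance < 0) msgs <- c(msgs, "tolerance must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
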