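#' Debye scattering profile of one frame
#'
#' Orientation-averaged scattering of a rigid set of beads,
#' I(q) = sum_u sum_v f_u f_v sin(q r_uv) / (q r_uv), with the q -> 0 limit
#' (sum f)^2 handled analytically (series branch of sin(x)/x below
#' x = 1e-4). Form factors default to 1 per bead; per-bead weights can be
#' supplied to emulate electron-count weighting.
#'
#' @param x an [Ensemble].
#' @param frame frame index.
#' @param molecule molecule index.
#' @param q momentum transfer grid, nm^-1 (non-negative).
#' @param formFactors optional per-bead form factors.
#' @return a [ScatteringProfile].
#' @export
debyeProfile <- function(x, frame = 1L, molecule = 1L, q, formFactors = NULL) {
  if (any(q < 0)) stop("argument error: q must be non-negative")
  mc <- moleculeCoords(x, molecule)
  xyz <- mc[, , frame, drop = TRUE]
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  f <- if (is.null(formFactors)) rep(1, nrow(xyz)) else formFactors
  scatteringProfile(q, cpp_debye(xyz, f, as.numeric(q)))
}

#' Ensemble-averaged Debye profile
#'
#' Per-q arithmetic mean of the per-frame Debye profiles of one molecule,
#' computed in one pass.
#'
#' @inheritParams debyeProfile
#' @param frames optional frame subset.
#' @return a [ScatteringProfile].
#' @export
ensembleDebyeProfile <- function(x, molecule = 1L, q, formFactors = NULL,
                                 frames = NULL) {
  if (any(q < 0)) stop("argument error: q must be non-negative")
  y <- if (is.null(frames)) x else subsetFrames(x, frames)
  top <- topology(y)
  nb1 <- beadsPerMolecule(top)
  sel <- as.integer((molecule - 1L) * nb1 + seq_len(nb1) - 1L)
  f <- if (is.null(formFactors)) rep(1, nb1) else formFactors
  I <- cpp_debye_ensemble(y@coords, dim(y@coords)[1], nFrames(y), sel, f,
                          as.numeric(q))
  scatteringProfile(q, I)
}

#' Average scattering profiles over an ensemble
#'
#' Per-q arithmetic mean of profiles on identical q grids.
#'
#' @param profiles list of [ScatteringProfile]s.
#' @return a [ScatteringProfile].
#' @export
ensembleProfile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  q <- profiles[[1]]@q
  for (p in profiles)
    if (!isTRUE(all.equal(p@q, q)))
      stop("argument error: profiles have mismatching q grids")
  I <- Reduce(`+`, lapply(profiles, slot, "intensity")) / length(profiles)
  scatteringProfile(q, I)
}

#' Analytic Debye function of a Gaussian chain
#'
#' I(q)/I(0) = 2 (exp(-x) + x - 1) / x^2 with x = q^2 <Rg^2>.
#'
#' @param q momentum transfer, nm^-1.
#' @param rg2 mean squared radius of gyration, nm^2.
#' @export
debyeFunction <- function(q, rg2) {
  x <- q^2 * rg2
  out <- ifelse(x < 1e-8, 1 - x / 3, 2 * (exp(-x) + x - 1) / x^2)
  as.numeric(out)
}

#' Fit a model scattering profile to a reference by scale and offset
#'
#' Minimizes chi^2(a, b) = (1/n) sum_i (I_ref(q_i) - a I_model(q_i) - b)^2
#' / sigma_i^2 over the scale a and offset b in closed form (weighted
#' linear regression). The model is evaluated at the reference q points by
#' linear interpolation when the grids differ.
#'
#' @param reference a [ScatteringProfile] with positive uncertainties.
#' @param model a [ScatteringProfile] covering the reference q range.
#' @return a [Chi2Fit].
#' @export
chi2Fit <- function(reference, model) {
  stopifnot(is(reference, "ScatteringProfile"), is(model, "ScatteringProfile"))
  if (!length(reference@sigma))
    stop("argument error: reference profile has no uncertainties")
  q <- reference@q
  if (min(q) < min(model@q) - 1e-9 || max(q) > max(model@q) + 1e-9)
    stop("argument error: model q grid does not cover the reference range")
  m <- if (isTRUE(all.equal(model@q, q))) model@intensity
       else stats::approx(model@q, model@intensity, xout = q)$y
  y <- reference@intensity
  w <- 1 / reference@sigma^2
  sw <- sum(w); swm <- sum(w * m); swy <- sum(w * y)
  swmm <- sum(w * m^2); swmy <- sum(w * m * y)
  det <- sw * swmm - swm^2
  if (det <= 0) stop("fit error: degenerate model profile (constant under weights)")
  a <- (sw * swmy - swm * swy) / det
  b <- (swmm * swy - swm * swmy) / det
  chi2 <- mean(w * (y - a * m - b)^2)
  new("Chi2Fit", a = a, bOffset = b, chi2 = max(chi2, 0), n = length(q))
}

setMethod("show", "Chi2Fit", function(object) {
  cat(sprintf("Chi2Fit: a = %.6g, b = %.6g, chi^2 = %.4g (n = %d)\n",
              object@a, object@bOffset, object@chi2, object@n))
})
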