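#' Inter-residue distance scaling curve
#'
#' Average inter-residue distance R(s) as a function of sequence separation
#' s = |i - j|, averaged over all frames and all same-separation residue
#' pairs within one domain of one molecule. Two averaging modes (arithmetic
#' mean of distances, or root mean square) and two residue-distance
#' definitions (smallest bead-bead distance between the residues, or the
#' backbone-bead distance) are offered; the ideal-chain closed forms hold
#' exactly in RMS/backbone mode.
#'
#' @param x an [Ensemble].
#' @param domain domain name (default: all residues of the molecule).
#' @param mode `"mean"` or `"rms"`.
#' @param distance `"minbead"` or `"backbone"`.
#' @param molecule molecule index.
#' @return a [ScalingCurve].
#' @export
scalingCurve <- function(x, domain = NULL, mode = c("mean", "rms"),
                         distance = c("minbead", "backbone"), molecule = 1L) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  top <- topology(x)
  sel <- if (is.null(domain)) seq_len(nResidues(top)) else domainResidues(top, domain)
  if (length(sel) < 3) stop("argument error: domain must have >= 3 residues")
  lay <- beadLayout(top)
  off <- (molecule - 1L) * lay$nResMol
  idx <- off + sel
  res <- cpp_scaling_curve(x@coords, dim(x@coords)[1], nFrames(x),
                           lay$beadStart[idx], lay$beadCount[idx],
                           lay$backbone[idx], lay$seq[idx],
                           distance == "backbone", mode == "rms")
  new("ScalingCurve", s = res$s, R = res$R, mode = mode, distance = distance,
      domain = if (is.null(domain)) "ALL" else domain)
}

setMethod("show", "ScalingCurve", function(object) {
  cat(sprintf("ScalingCurve (%s, %s distances) over domain %s: s = 1..%d\n",
              object@mode, object@distance, object@domain, max(object@s)))
})

#' Fit the Flory scaling law R(s) = b s^nu
#'
#' Nonlinear least squares on the scaling curve over separations
#' `s >= sMin`. The Kuhn length b is fixed at 0.55 nm by default (the value
#' commonly adopted for disordered proteins); pass `bFixed = NA` to fit b
#' and nu jointly.
#'
#' @param curve a [ScalingCurve] (or list/data.frame with `s`, `R`).
#' @param bFixed Kuhn length to hold fixed, nm, or `NA` to fit it.
#' @param sMin smallest separation included (default 2: the bonded pair is
#'   geometry- rather than statistics-dominated).
#' @return a [FloryFit].
#' @export
fitFlory <- function(curve, bFixed = 0.55, sMin = 2) {
  s <- if (is(curve, "ScalingCurve")) curve@s else curve$s
  R <- if (is(curve, "ScalingCurve")) curve@R else curve$R
  keep <- s >= sMin
  s <- s[keep]; R <- R[keep]
  if (length(s) < 5) stop("argument error: need >= 5 separation points")
  ## log-log regression start values
  lf <- stats::lm(log(R) ~ log(s))
  nu0 <- min(max(unname(stats::coef(lf)[2]), 0.05), 0.95)
  b0 <- exp(unname(stats::coef(lf)[1]))
  df <- data.frame(s = s, R = R)
  fit <- tryCatch({
    if (is.na(bFixed)) {
      minpack.lm::nlsLM(R ~ b * s^nu, data = df,
                        start = list(b = b0, nu = nu0),
                        lower = c(1e-6, 1e-3), upper = c(Inf, 0.999),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(R ~ bFixed * s^nu, data = df,
                        start = list(nu = nu0),
                        lower = 1e-3, upper = 0.999,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e)
    stop("fit error: Flory fit did not converge (", conditionMessage(e), ")"))
  cf <- stats::coef(fit)
  b <- if (is.na(bFixed)) unname(cf["b"]) else bFixed
  nu <- unname(cf["nu"])
  new("FloryFit", b = b, nu = nu, bFixed = !is.na(bFixed),
      residual = sqrt(mean(stats::resid(fit)^2)), sMin = sMin)
}

setMethod("show", "FloryFit", function(object) {
  cat(sprintf("FloryFit: b = %.4g nm (%s), nu = %.4g, rms residual %.3g nm\n",
              object@b, if (object@bFixed) "fixed" else "fitted", object@nu,
              object@residual))
})

#' Locate the theta point on a scaling-exponent scan
#'
#' Fits a smooth monotone curve (isotonic regression followed by a
#' shape-preserving monotone cubic interpolant) to scan points
#' (control value, fitted nu) and returns the control value at which the
#' smoothed curve crosses nu = 1/2 — the theta point, where chain
#' statistics are ideal. A crossing is reported only when 1/2 is bracketed
#' by the smoothed curve.
#'
#' @param control scan control values (e.g. an interaction rescaling factor
#'   or a pair-well depth), >= 3 points.
#' @param nu fitted scaling exponents at the scan points.
#' @return a [ThetaScan]; its `crossing` slot is `NA` when nu = 1/2 is not
#'   bracketed.
#' @export
thetaScan <- function(control, nu) {
  stopifnot(length(control) == length(nu))
  if (length(control) < 3) stop("argument error: need >= 3 scan points")
  o <- order(control)
  control <- control[o]; nu <- nu[o]
  ## isotonic regression in the dominant direction, then monotone cubic
  increasing <- stats::cor(control, nu) >= 0
  iso <- if (increasing) stats::isoreg(control, nu)$yf
         else -stats::isoreg(control, -nu)$yf
  fn <- stats::splinefun(control, iso, method = "hyman")
  grid <- seq(control[1], control[length(control)], length.out = 512)
  gv <- fn(grid)
  crossing <- NA_real_
  if ((min(gv) - 0.5) * (max(gv) - 0.5) <= 0 && min(gv) != max(gv)) {
    sgn <- sign(gv - 0.5)
    flip <- which(diff(sgn) != 0 | sgn[-1] == 0)
    if (length(flip)) {
      lo <- grid[flip[1]]; hi <- grid[flip[1] + 1]
      crossing <- if (fn(lo) == 0.5) lo else
        stats::uniroot(function(z) fn(z) - 0.5, c(lo, hi), tol = 1e-10)$root
    }
  }
  new("ThetaScan", control = control, nu = nu, crossing = crossing,
      grid = data.frame(control = grid, nu = gv))
}

setMethod("show", "ThetaScan", function(object) {
  cat(sprintf("ThetaScan: %d point(s), nu in [%.3g, %.3g]; ",
              length(object@control), min(object@nu), max(object@nu)))
  if (is.na(object@crossing)) cat("no crossing of nu = 1/2\n")
  else cat(sprintf("theta point at control = %.6g\n", object@crossing))
})

#' Fit the Gaussian-chain end-to-end distance distribution
#'
#' Builds a normalized histogram of the end-to-end distance samples
#' (default 50 equal-width bins over `[0, max(samples)]`, empty bins kept
#' with zero density) and least-squares fits the Gaussian-chain density
#' p(d) = 4 d^2 exp[-(d/xi)^2] / (sqrt(pi) xi^3) for the scale parameter
#' xi. The goodness of fit is the squared Pearson correlation between the
#' histogram densities and the fitted densities at the bin centres.
#'
#' @param samples end-to-end distances, nm (>= 100 values), or a
#'   precomputed histogram as a list with `mid` and `density`.
#' @param bins number of histogram bins.
#' @return a [GaussianChainFit].
#' @export
fitGaussianDee <- function(samples, bins = 50L) {
  if (is.list(samples)) {
    mids <- samples$mid
    dens <- samples$density
  } else {
    if (length(samples) < 100) stop("argument error: need >= 100 samples")
    brk <- seq(0, max(samples), length.out = bins + 1L)
    h <- graphics::hist(samples, breaks = brk, plot = FALSE)
    mids <- h$mids
    dens <- h$density
  }
  if (sum(dens > 0) < 2)
    stop("fit error: degenerate histogram (fewer than two occupied bins)")
  xi0 <- sum(mids * dens) / sum(dens) * sqrt(pi) / 2  # from mean = 2 xi/sqrt(pi)
  df <- data.frame(d = mids, p = dens)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ 4 * d^2 * exp(-(d / xi)^2) / (sqrt(pi) * xi^3),
                      data = df, start = list(xi = xi0), lower = 1e-8,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit error: Gaussian-chain fit did not converge (",
           conditionMessage(e), ")"))
  xi <- unname(stats::coef(fit)["xi"])
  fitted <- gaussianDeeDensity(mids, xi)
  r2 <- stats::cor(dens, fitted)^2
  new("GaussianChainFit", xi = xi, r2 = r2, binCenters = mids,
      density = dens, fitted = fitted)
}

setMethod("show", "GaussianChainFit", function(object) {
  cat(sprintf("GaussianChainFit: xi = %.4g nm, R^2 = %.4f\n",
              object@xi, object@r2))
})
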