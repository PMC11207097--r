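#' Radius of gyration per frame
#'
#' Root mean squared distance of a molecule's beads from their centroid.
#' Beads are weighted equally by default; optional per-bead weights are
#' accepted (e.g. approximate bead masses).
#'
#' @param x an [Ensemble].
#' @param molecule molecule index.
#' @param weights optional per-bead weights (length = beads per molecule).
#' @return numeric vector, one value per frame, nm.
#' @export
radiusOfGyration <- function(x, molecule = 1L, weights = NULL) {
  mc <- moleculeCoords(x, molecule)
  nb <- dim(mc)[1]; nf <- dim(mc)[3]
  if (is.null(weights)) weights <- rep(1, nb)
  w <- weights / sum(weights)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- mc[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    ctr <- colSums(xyz * w)
    out[f] <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
  }
  out
}

#' Maximum diameter per frame
#'
#' The largest distance between any pair of a molecule's beads, by
#' exhaustive pairwise search. A single-bead molecule yields 0 with a
#' warning.
#'
#' @inheritParams radiusOfGyration
#' @return numeric vector, one value per frame, nm.
#' @export
maxDiameter <- function(x, molecule = 1L) {
  mc <- moleculeCoords(x, molecule)
  nb <- dim(mc)[1]; nf <- dim(mc)[3]
  if (nb < 2) {
    warning("single-bead molecule: maximum diameter is 0")
    return(numeric(nf))
  }
  vapply(seq_len(nf), function(f) cpp_max_diameter(mc[, , f]), numeric(1))
}

#' End-to-end distance per frame
#'
#' Euclidean distance between the backbone beads of the first and last
#' residues of a molecule.
#'
#' @inheritParams radiusOfGyration
#' @return numeric vector, one value per frame, nm.
#' @export
endToEnd <- function(x, molecule = 1L) {
  top <- topology(x)
  r <- top@residues
  if (anyNA(r$backbone)) stop("topology error: backbone beads not designated")
  start1 <- cumsum(c(0L, r$nBeads))
  bFirst <- start1[1] + r$backbone[1]
  bLast <- start1[nrow(r)] + r$backbone[nrow(r)]
  mc <- moleculeCoords(x, molecule)
  dif <- matrix(mc[bFirst, , ] - mc[bLast, , ], nrow = 3)
  sqrt(colSums(dif^2))
}

#' Per-frame size metrics of a molecule
#'
#' @inheritParams radiusOfGyration
#' @return data.frame with columns `time`, `rg`, `dmax`, `dee`.
#' @export
conformerMetrics <- function(x, molecule = 1L) {
  data.frame(time = frameTimes(x),
             rg = radiusOfGyration(x, molecule),
             dmax = maxDiameter(x, molecule),
             dee = endToEnd(x, molecule))
}

defaultBlockSizes <- function(n) {
  kmax <- floor(log2(max(n %/% 32, 2)))
  unique(as.integer(2^(0:kmax)))
}

#' Block error analysis of a correlated series
#'
#' For each block size the series is cut into contiguous blocks and the
#' standard error of the block means is computed; the reported error is the
#' plateau value (by default, the standard error at the largest block size).
#' For positively correlated series this exceeds the naive standard error.
#'
#' @param series numeric vector.
#' @param blockSizes integer vector of block sizes; defaults to powers of
#'   two up to n/32. The series must be at least 4 times the largest block.
#' @return list with `error` (the plateau standard error) and `table`
#'   (data.frame of `blockSize`, `nBlocks`, `se`).
#' @export
blockError <- function(series, blockSizes = NULL) {
  n <- length(series)
  if (is.null(blockSizes)) blockSizes <- defaultBlockSizes(n)
  blockSizes <- sort(unique(as.integer(blockSizes)))
  if (n < 4 * max(blockSizes))
    stop("argument error: series must be at least 4x the largest block size")
  tab <- do.call(rbind, lapply(blockSizes, function(m) {
    nb <- n %/% m
    bm <- colMeans(matrix(series[seq_len(nb * m)], nrow = m))
    data.frame(blockSize = m, nBlocks = nb,
               se = stats::sd(bm) / sqrt(nb))
  }))
  list(error = tab$se[nrow(tab)], table = tab)
}

#' Mean, block error and normalized histogram of a series
#'
#' @param series numeric vector (e.g. a per-frame observable).
#' @param bins number of equal-width histogram bins over the observed range.
#' @param blockSizes passed to [blockError()].
#' @return a [SeriesSummary]; the histogram densities integrate to 1.
#' @export
seriesSummary <- function(series, bins = 50L, blockSizes = NULL) {
  be <- blockError(series, blockSizes)
  rng <- range(series)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(series, breaks = brk, plot = FALSE)
  hist <- data.frame(lower = brk[-length(brk)], upper = brk[-1],
                     mid = h$mids, density = h$density)
  new("SeriesSummary", mean = mean(series), blockError = be$error,
      blockTable = be$table, histogram = hist)
}

setMethod("show", "SeriesSummary", function(object) {
  cat(sprintf("SeriesSummary: mean = %.6g +/- %.3g (block error, block size %d)\n",
              object@mean, object@blockError,
              object@blockTable$blockSize[nrow(object@blockTable)]))
})
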