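#' Construct an ensemble from a coordinate array
#'
#' @param topology a [BeadTopology].
#' @param coords numeric array `[beads, 3, frames]` in nm.
#' @param time frame times in ns (defaults to 0, 1, 2, ...).
#' @param boxEdge cubic box edge(s) in nm, recycled over frames (`NA` for
#'   no box).
#' @return an [Ensemble].
#' @export
ensemble <- function(topology, coords, time = NULL, boxEdge = NA_real_) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  new("Ensemble", topology = topology, coords = coords,
      time = as.numeric(time), boxEdge = rep_len(as.numeric(boxEdge), nf))
}

#' @rdname Ensemble-class
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3])

#' @rdname Ensemble-class
#' @export
setMethod("nMolecules", "Ensemble", function(x) x@topology@nMolecules)

#' @rdname Ensemble-class
#' @export
setMethod("nResidues", "Ensemble", function(x) nResidues(x@topology))

#' @rdname Ensemble-class
#' @export
setMethod("topology", "Ensemble", function(x) x@topology)

#' @rdname Ensemble-class
#' @export
setMethod("boxEdges", "Ensemble", function(x) x@boxEdge)

#' @rdname Ensemble-class
#' @export
setMethod("frameTimes", "Ensemble", function(x) x@time)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Ensemble", function(x, i) {
  stopifnot(length(i) == 1, i >= 1, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' Coordinates of one molecule (all frames or one frame)
#'
#' @param x an [Ensemble].
#' @param molecule molecule index (1-based).
#' @return array `[beads, 3, frames]` for that molecule.
#' @export
moleculeCoords <- function(x, molecule = 1L) {
  nb1 <- beadsPerMolecule(x@topology)
  if (molecule < 1 || molecule > nMolecules(x))
    stop("ensemble has no molecule ", molecule)
  idx <- (molecule - 1L) * nb1 + seq_len(nb1)
  x@coords[idx, , , drop = FALSE]
}

#' @rdname stride
#' @export
setMethod("stride", "Ensemble", function(x, k) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1) stop("stride k must be a single integer >= 1")
  keep <- seq(1L, nFrames(x), by = k)
  new("Ensemble", topology = x@topology,
      coords = x@coords[, , keep, drop = FALSE],
      time = x@time[keep], boxEdge = x@boxEdge[keep])
})

#' Subset an ensemble by frame index
#' @param x an [Ensemble].
#' @param frames integer vector of frame indices to keep.
#' @export
subsetFrames <- function(x, frames) {
  frames <- as.integer(frames)
  stopifnot(all(frames >= 1), all(frames <= nFrames(x)))
  new("Ensemble", topology = x@topology,
      coords = x@coords[, , frames, drop = FALSE],
      time = x@time[frames], boxEdge = x@boxEdge[frames])
}

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d frame(s), %d molecule(s) x %d bead(s)\n",
              nFrames(object), nMolecules(object),
              beadsPerMolecule(object@topology)))
  bx <- object@boxEdge[1]
  if (!is.na(bx)) cat(sprintf("  cubic box edge: %.3g nm\n", bx))
  cat(sprintf("  time range: %.4g .. %.4g ns\n",
              object@time[1], object@time[nFrames(object)]))
})
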