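#' @rdname Ensemble-class
#' @param object,x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble-class
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname BeadTopology-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Ensemble-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname Ensemble-class
#' @export
setGeneric("boxEdges", function(x) standardGeneric("boxEdges"))

#' @rdname Ensemble-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Extract the coordinate matrix of one frame
#'
#' @param x an [Ensemble].
#' @param i frame index.
#' @return numeric matrix `[beads, 3]`, nm.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname BeadTopology-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname BeadTopology-class
#' @export
setGeneric("strands", function(x) standardGeneric("strands"))

#' @rdname ScatteringProfile-class
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname ScatteringProfile-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ScatteringProfile-class
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname ContactMap-class
#' @export
setGeneric("contactProbabilities", function(x) standardGeneric("contactProbabilities"))

#' @rdname ContactMap-class
#' @export
setGeneric("contactErrors", function(x) standardGeneric("contactErrors"))

#' Keep every k-th frame of an ensemble
#'
#' Keeps frames 1, k+1, 2k+1, ... (the first frame and then every k-th),
#' so the result has `ceiling(N / k)` frames. `stride(x, 1)` is the
#' identity.
#'
#' @param x an [Ensemble].
#' @param k stride, a single integer >= 1.
#' @return the strided [Ensemble].
#' @export
setGeneric("stride", function(x, k) standardGeneric("stride"))
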