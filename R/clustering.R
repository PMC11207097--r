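#' Oligomer partition of one frame by agglomerative contact clustering
#'
#' Starts from singleton clusters (one per molecule) and repeatedly merges
#' two clusters whenever any molecule of one makes at least one
#' inter-molecular contact (any bead pair within the cutoff, minimum-image
#' convention) with any molecule of the other, until no merge is possible.
#' The fixed point equals the connected components of the molecule contact
#' graph.
#'
#' @param x an [Ensemble] with >= 2 molecules and a box edge.
#' @param frame frame index.
#' @param cutoff contact cutoff, nm.
#' @return integer vector of cluster labels (1-based, ordered by first
#'   member) per molecule.
#' @export
frameClusters <- function(x, frame = 1L, cutoff = DEFAULT_CUTOFF) {
  nm <- nMolecules(x)
  if (nm < 2) {
    warning("single molecule: trivial partition")
    return(1L)
  }
  L <- boxEdges(x)[frame]
  if (is.na(L)) stop("argument error: clustering needs a box edge")
  lay <- beadLayout(topology(x))
  adj <- cpp_mol_contacts(frameCoords(x, frame), lay$beadMol, nm, cutoff, L)
  ## agglomerative merging until no two clusters share a contacting pair
  labels <- seq_len(nm)
  repeat {
    merged <- FALSE
    for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
      if (labels[a] != labels[b] && adj[a, b]) {
        labels[labels == labels[b]] <- labels[a]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  as.integer(match(labels, unique(labels)))
}

#' Cluster-count time series and histograms over an ensemble
#'
#' Applies [frameClusters()] to every frame and summarizes the number of
#' clusters and the size of the largest cluster, with normalized histograms
#' over 1..n_molecules.
#'
#' @param x an [Ensemble] with >= 2 molecules and box edges.
#' @param cutoff contact cutoff, nm.
#' @return a [ClusterSeries].
#' @export
clusterSeries <- function(x, cutoff = DEFAULT_CUTOFF) {
  nm <- nMolecules(x)
  nf <- nFrames(x)
  parts <- lapply(seq_len(nf), function(f) frameClusters(x, f, cutoff))
  nClusters <- vapply(parts, function(p) length(unique(p)), integer(1))
  largest <- vapply(parts, function(p) max(tabulate(p)), integer(1))
  histOf <- function(v) {
    h <- tabulate(v, nbins = nm) / length(v)
    names(h) <- seq_len(nm)
    h
  }
  new("ClusterSeries", nClusters = nClusters, largestCluster = largest,
      histNClusters = histOf(nClusters), histLargest = histOf(largest),
      partitions = parts)
}

setMethod("show", "ClusterSeries", function(object) {
  cat(sprintf("ClusterSeries: %d frame(s); most likely cluster count %s; largest cluster most typically %s molecule(s)\n",
              length(object@nClusters),
              names(which.max(object@histNClusters)),
              names(which.max(object@histLargest))))
})
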