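DEFAULT_CUTOFF <- 0.7      # nm, residue contact cutoff
DEFAULT_NIGNORE <- 3L      # (i,i+1..i+3) pairs excluded within a molecule

interCheck <- function(x) {
  if (nMolecules(x) < 2)
    stop("argument error: inter scope needs >= 2 molecules")
  if (anyNA(boxEdges(x)))
    stop("argument error: inter scope needs a box edge on every frame")
}

#' Residue contacts of a single frame
#'
#' Two residues are in contact when the smallest distance between any bead
#' of one and any bead of the other is below the cutoff (0.7 nm by
#' default). Within a molecule, pairs closer in sequence than
#' `nNeighborsIgnored + 1` are excluded; across molecules all pairs are
#' eligible and distances follow the minimum-image convention on the cubic
#' box.
#'
#' @param x an [Ensemble].
#' @param frame frame index.
#' @param scope `"intra"` or `"inter"`.
#' @param cutoff contact cutoff, nm.
#' @param nNeighborsIgnored number of sequence neighbours excluded (intra).
#' @return data.frame with columns `molI`, `i`, `molJ`, `j` (per-molecule
#'   1-based residue indices), one row per contacting pair.
#' @export
frameContacts <- function(x, frame = 1L, scope = c("intra", "inter"),
                          cutoff = DEFAULT_CUTOFF,
                          nNeighborsIgnored = DEFAULT_NIGNORE) {
  scope <- match.arg(scope)
  if (scope == "inter") interCheck(x)
  lay <- beadLayout(topology(x))
  L <- boxEdges(x)[frame]
  m <- cpp_residue_contacts(frameCoords(x, frame), lay$beadStart,
                            lay$beadCount, lay$mol, lay$seq, cutoff,
                            as.integer(nNeighborsIgnored), scope == "inter",
                            if (is.na(L)) -1 else L)
  idx <- which(m & upper.tri(m, diag = FALSE), arr.ind = TRUE)
  data.frame(molI = lay$mol[idx[, 1]] + 1L, i = lay$seq[idx[, 1]],
             molJ = lay$mol[idx[, 2]] + 1L, j = lay$seq[idx[, 2]])
}

blockIds <- function(nf, nBlocks) as.integer(floor((seq_len(nf) - 1) * nBlocks / nf))

#' Residue-pair contact probability map over an ensemble
#'
#' The probability of a contact is the number of frames in which it is
#' present divided by the total number of frames (for intra scope with
#' several molecules, molecule-frames). Per-pair errors come from block
#' error analysis over contiguous frame blocks; the per-block frequencies
#' are retained for significance testing with [compareMaps()].
#'
#' @inheritParams frameContacts
#' @param nBlocks number of contiguous frame blocks.
#' @return a [ContactMap] over per-molecule residue indices.
#' @export
contactProbabilityMap <- function(x, scope = c("intra", "inter"),
                                  cutoff = DEFAULT_CUTOFF,
                                  nNeighborsIgnored = DEFAULT_NIGNORE,
                                  nBlocks = 10L) {
  scope <- match.arg(scope)
  if (scope == "inter") interCheck(x)
  top <- topology(x)
  lay <- beadLayout(top)
  nf <- nFrames(x)
  nBlocks <- min(as.integer(nBlocks), nf)
  bid <- blockIds(nf, nBlocks)
  box <- ifelse(is.na(boxEdges(x)), -1, boxEdges(x))
  counts <- cpp_contact_map_ensemble(x@coords, dim(x@coords)[1], nf,
                                     lay$beadStart, lay$beadCount, lay$mol,
                                     lay$seq, lay$nResMol, lay$nMol, cutoff,
                                     as.integer(nNeighborsIgnored),
                                     scope == "inter", box, bid, nBlocks)
  perBlockFrames <- tabulate(bid + 1L, nBlocks)
  denom <- if (scope == "intra") perBlockFrames * lay$nMol else perBlockFrames
  blockMeans <- sweep(counts, 3, denom, "/")
  p <- apply(counts, c(1, 2), sum) / sum(denom)
  err <- apply(blockMeans, c(1, 2), stats::sd) / sqrt(nBlocks)
  nres <- lay$nResMol
  seqd <- abs(outer(seq_len(nres), seq_len(nres), "-"))
  eligible <- if (scope == "intra") seqd > nNeighborsIgnored
              else matrix(TRUE, nres, nres)
  new("ContactMap", probability = p, error = err, blockMeans = blockMeans,
      eligible = eligible, scope = scope, nFrames = nf, cutoff = cutoff,
      nNeighborsIgnored = as.integer(nNeighborsIgnored))
}

#' @rdname ContactMap-class
#' @export
setMethod("contactProbabilities", "ContactMap", function(x) x@probability)

#' @rdname ContactMap-class
#' @export
setMethod("contactErrors", "ContactMap", function(x) x@error)

setMethod("show", "ContactMap", function(object) {
  npair <- sum(object@eligible & upper.tri(object@eligible, diag = TRUE))
  nhit <- sum(object@probability[object@eligible &
                                   upper.tri(object@eligible, diag = TRUE)] > 0)
  cat(sprintf("ContactMap (%s): %d residues, %d/%d eligible pairs observed in contact, %d frame(s)\n",
              object@scope, nrow(object@probability), nhit, npair,
              object@nFrames))
})

#' Contact-map edge list
#' @param x a [ContactMap].
#' @param minProbability report only pairs with probability above this.
#' @return data.frame `i`, `j`, `p`, `err`.
#' @export
contactEdgeList <- function(x, minProbability = 0) {
  idx <- which(upper.tri(x@probability, diag = x@scope == "inter") &
                 x@eligible & x@probability > minProbability, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             p = x@probability[idx], err = x@error[idx])
}

#' Render a contact map on a decimal-log probability scale
#'
#' @param x a [ContactMap].
#' @param floor probabilities below this are shown as empty.
#' @param ... passed to [graphics::image()].
#' @export
plotContactMap <- function(x, floor = 1e-4, ...) {
  p <- x@probability
  lp <- log10(pmax(p, floor))
  lp[p < floor] <- NA
  n <- nrow(p)
  graphics::image(seq_len(n), seq_len(n), lp,
                  col = gray(seq(0.95, 0, length.out = 64)),
                  xlab = "residue index", ylab = "residue index", ...)
  invisible(x)
}

resolveDomainSets <- function(top) {
  doms <- domains(top)
  lapply(doms, function(iv) iv[1]:iv[2])
}

#' Residue-vs-domain and strand-vs-domain contact probabilities
#'
#' For intra scope, `residueProb[i, D]` is the fraction of frames (and
#' molecules) in which residue i contacts at least one residue of domain D
#' of the same molecule, with the usual near-diagonal exclusion. For inter
#' scope the contacted domain belongs to another molecule (minimum-image
#' convention), and additionally the domain-domain matrix holds the
#' fraction of frames with at least one D1-D2 cross-molecule contact.
#' Strand rows give the probability that any residue of the beta strand
#' contacts the domain. All errors are block errors over frames.
#'
#' @inheritParams contactProbabilityMap
#' @return a [DomainContactProfile].
#' @export
domainProfile <- function(x, scope = c("intra", "inter"),
                          cutoff = DEFAULT_CUTOFF,
                          nNeighborsIgnored = DEFAULT_NIGNORE,
                          nBlocks = 10L) {
  scope <- match.arg(scope)
  if (scope == "inter") interCheck(x)
  top <- topology(x)
  if (!length(domains(top))) stop("topology error: no domain annotation")
  domSets <- resolveDomainSets(top)
  strSets <- lapply(strands(top), function(iv) iv[1]:iv[2])
  lay <- beadLayout(top)
  nres <- lay$nResMol; nm <- lay$nMol; nf <- nFrames(x)
  nD <- length(domSets); nS <- length(strSets)
  nBlocks <- min(as.integer(nBlocks), nf)
  bid <- blockIds(nf, nBlocks)
  perBlockFrames <- tabulate(bid + 1L, nBlocks)

  resAcc <- array(0, c(nres, nD, nBlocks))
  strAcc <- array(0, c(max(nS, 1L), nD, nBlocks))
  domAcc <- array(0, c(nD, nD, nBlocks))
  rows <- lapply(seq_len(nm), function(m) (m - 1L) * nres + seq_len(nres))
  for (f in seq_len(nf)) {
    L <- boxEdges(x)[f]
    M <- cpp_residue_contacts(frameCoords(x, f), lay$beadStart, lay$beadCount,
                              lay$mol, lay$seq, cutoff,
                              as.integer(nNeighborsIgnored),
                              scope == "inter", if (is.na(L)) -1 else L)
    blk <- bid[f] + 1L
    if (scope == "intra") {
      for (m in seq_len(nm)) {
        sub <- M[rows[[m]], rows[[m]], drop = FALSE]
        for (d in seq_len(nD)) {
          hit <- rowSums(sub[, domSets[[d]], drop = FALSE]) > 0
          resAcc[, d, blk] <- resAcc[, d, blk] + hit
          if (nS)
            for (k in seq_len(nS))
              strAcc[k, d, blk] <- strAcc[k, d, blk] + any(hit[strSets[[k]]])
        }
      }
    } else {
      for (m in seq_len(nm)) {
        others <- unlist(rows[-m])
        cross <- M[rows[[m]], others, drop = FALSE]
        otherSeq <- rep(seq_len(nres), nm - 1L)
        for (d in seq_len(nD)) {
          cols <- otherSeq %in% domSets[[d]]
          hit <- rowSums(cross[, cols, drop = FALSE]) > 0
          resAcc[, d, blk] <- resAcc[, d, blk] + hit
          if (nS)
            for (k in seq_len(nS))
              strAcc[k, d, blk] <- strAcc[k, d, blk] + any(hit[strSets[[k]]])
        }
      }
      ## domain-domain union event per frame (any molecule pair)
      for (d1 in seq_len(nD)) for (d2 in d1:nD) {
        hit <- FALSE
        for (m in seq_len(nm)) {
          others <- unlist(rows[-m])
          otherSeq <- rep(seq_len(nres), nm - 1L)
          cross <- M[rows[[m]][domSets[[d1]]],
                     others[otherSeq %in% domSets[[d2]]], drop = FALSE]
          if (any(cross)) { hit <- TRUE; break }
        }
        if (hit) {
          domAcc[d1, d2, blk] <- domAcc[d1, d2, blk] + 1
          if (d1 != d2) domAcc[d2, d1, blk] <- domAcc[d2, d1, blk] + 1
        }
      }
    }
  }
  denomRes <- if (scope == "intra") perBlockFrames * nm else perBlockFrames * nm
  bmRes <- sweep(resAcc, 3, denomRes, "/")
  bmStr <- sweep(strAcc, 3, denomRes, "/")
  bmDom <- sweep(domAcc, 3, perBlockFrames, "/")
  wmean <- function(a, den) apply(sweep(a, 3, den, "*"), c(1, 2), sum) / sum(den)
  berr <- function(bm) apply(bm, c(1, 2), stats::sd) / sqrt(nBlocks)
  dn <- names(domSets)
  resP <- wmean(bmRes, denomRes); dimnames(resP) <- list(NULL, dn)
  strP <- wmean(bmStr, denomRes)
  if (nS) dimnames(strP) <- list(names(strSets), dn)
  domP <- if (scope == "inter") wmean(bmDom, perBlockFrames) else matrix(0, 0, 0)
  if (scope == "inter") dimnames(domP) <- list(dn, dn)
  new("DomainContactProfile",
      residueProb = resP, residueErr = berr(bmRes),
      strandProb = if (nS) strP else matrix(0, 0, nD),
      strandErr = if (nS) berr(bmStr) else matrix(0, 0, nD),
      domainProb = domP,
      domainErr = if (scope == "inter") berr(bmDom) else matrix(0, 0, 0),
      scope = scope)
}

setMethod("show", "DomainContactProfile", function(object) {
  cat(sprintf("DomainContactProfile (%s): %d residue(s) x %d domain(s)",
              object@scope, nrow(object@residueProb), ncol(object@residueProb)))
  if (nrow(object@strandProb)) cat(sprintf(", %d strand(s)", nrow(object@strandProb)))
  cat("\n")
  if (length(object@domainProb)) {
    cat("  domain-domain contact probabilities:\n")
    print(round(object@domainProb, 4))
  }
})

#' Compare two contact maps with per-pair ANOVA on block means
#'
#' For every eligible residue pair, the per-block contact frequencies of
#' the two maps are treated as replicates of a one-way ANOVA (two groups);
#' a pair enters the significance mask of a threshold when its p-value is
#' below the threshold and the absolute probability difference exceeds
#' `minDelta`. Masks are nested across thresholds by construction.
#'
#' @param mapA,mapB [ContactMap]s built with stored block means over the
#'   same residue grid.
#' @param thresholds p-value thresholds for the masks.
#' @param minDelta minimum |p_A - p_B| for a pair to be flagged.
#' @return a [MapComparison].
#' @export
compareMaps <- function(mapA, mapB, thresholds = c(0.05, 0.01, 0.005),
                        minDelta = 0.001) {
  stopifnot(is(mapA, "ContactMap"), is(mapB, "ContactMap"))
  if (!identical(dim(mapA@probability), dim(mapB@probability)))
    stop("argument error: maps cover different residue grids")
  nA <- dim(mapA@blockMeans)[3]
  nB <- dim(mapB@blockMeans)[3]
  if (nA < 2 || nB < 2)
    stop("argument error: both maps need >= 2 blocks")
  a <- mapA@blockMeans; b <- mapB@blockMeans
  mA <- apply(a, c(1, 2), mean); mB <- apply(b, c(1, 2), mean)
  vA <- apply(a, c(1, 2), stats::var); vB <- apply(b, c(1, 2), stats::var)
  gm <- (nA * mA + nB * mB) / (nA + nB)
  ssb <- nA * (mA - gm)^2 + nB * (mB - gm)^2
  ssw <- (nA - 1) * vA + (nB - 1) * vB
  df2 <- nA + nB - 2
  Fv <- (ssb / 1) / (ssw / df2)
  p <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1       # identical constant groups
  p[ssw == 0 & ssb > 0] <- 0        # separated constant groups
  delta <- abs(mapA@probability - mapB@probability)
  eligible <- mapA@eligible & mapB@eligible
  thresholds <- sort(thresholds, decreasing = TRUE)
  masks <- lapply(thresholds, function(th) eligible & p < th & delta > minDelta)
  names(masks) <- as.character(thresholds)
  new("MapComparison", delta = delta, pValue = p, masks = masks,
      thresholds = thresholds, minDelta = minDelta)
}

setMethod("show", "MapComparison", function(object) {
  cat("MapComparison: |delta| up to", format(max(object@delta), digits = 4), "\n")
  for (th in names(object@masks))
    cat(sprintf("  p < %s & |delta| > %g: %d pair entrie(s) flagged\n",
                th, object@minDelta, sum(object@masks[[th]])))
})
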