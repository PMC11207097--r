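#' Construct a scattering profile
#'
#' @param q momentum transfer grid, nm^-1 (strictly increasing).
#' @param intensity I(q), arbitrary units.
#' @param sigma optional per-point uncertainties (positive).
#' @return a [ScatteringProfile].
#' @export
scatteringProfile <- function(q, intensity, sigma = numeric(0)) {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma))
}

#' @rdname ScatteringProfile-class
#' @export
setMethod("qValues", "ScatteringProfile", function(x) x@q)

#' @rdname ScatteringProfile-class
#' @export
setMethod("intensities", "ScatteringProfile", function(x) x@intensity)

#' @rdname ScatteringProfile-class
#' @export
setMethod("sigmas", "ScatteringProfile", function(x) x@sigma)

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d point(s), q in [%.4g, %.4g] nm^-1%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with uncertainties" else ""))
})

beadNamesOf <- function(top) {
  unlist(lapply(seq_len(nResidues(top)), function(i) {
    nb <- top@residues$nBeads[i]
    nm <- rep("", nb)
    sc <- 1L
    for (k in seq_len(nb)) {
      if (k == top@residues$backbone[i]) nm[k] <- "BB"
      else { nm[k] <- paste0("SC", sc); sc <- sc + 1L }
    }
    nm
  }))
}

#' Read a conformational ensemble from disk
#'
#' Supports multi-model PDB (`MODEL`/`ENDMDL`; coordinates in Angstrom on
#' disk, converted to nm) and XYZ trajectories (coordinates already in nm;
#' a `box=` entry on the comment line carries the cubic box edge). The bead
#' count of every frame must match the topology.
#'
#' @param coordinatePath path to the coordinate file.
#' @param topology a [BeadTopology], or the path of a JSON topology config.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return an [Ensemble] with frames in file order.
#' @export
readEnsemble <- function(coordinatePath, topology, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (is.character(topology)) topology <- readTopology(topology)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(coordinatePath))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "pdb") readEnsemblePDB(coordinatePath, topology)
  else readEnsembleXYZ(coordinatePath, topology)
}

readEnsemblePDB <- function(path, top) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                     # [frames, 3*natoms], Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natoms <- ncol(xyz) / 3
  nbExp <- beadsPerMolecule(top) * top@nMolecules
  if (natoms != nbExp)
    stop(sprintf("topology error: frame 1 has %d beads, topology expects %d",
                 natoms, nbExp))
  nf <- nrow(xyz)
  coords <- array(0, c(natoms, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  box <- NA_real_
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) {
    L <- suppressWarnings(as.numeric(substr(cl[1], 7, 15))) / 10
    if (!is.na(L) && L > 1e-3) box <- L
  }
  ensemble(top, coords, boxEdge = box)
}

readEnsembleXYZ <- function(path, top) {
  lines <- readLines(path, warn = FALSE)
  nbExp <- beadsPerMolecule(top) * top@nMolecules
  frames <- list(); times <- numeric(); boxes <- numeric()
  ln <- 1L; f <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    nb <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nb)) stop(sprintf("parse error at line %d: expected a bead count", ln))
    f <- f + 1L
    if (nb != nbExp)
      stop(sprintf("topology error: frame %d has %d beads, topology expects %d",
                   f, nb, nbExp))
    if (ln + 1L + nb > length(lines))
      stop(sprintf("parse error at line %d: truncated frame %d", length(lines), f))
    comment <- lines[ln + 1L]
    tm <- regmatches(comment, regexec("time=\\s*([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment, regexec("box=\\s*([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else f - 1)
    boxes <- c(boxes, if (length(bx) == 2) as.numeric(bx[2]) else NA_real_)
    block <- lines[(ln + 2L):(ln + 1L + nb)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 'name x y z'", ln + 1L + bad[1]))
    m <- matrix(suppressWarnings(as.numeric(t(vapply(parts, function(p) p[2:4],
                                                     character(3))))), ncol = 3)
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1]
      stop(sprintf("parse error at line %d: non-numeric coordinate", ln + 1L + bad))
    }
    frames[[f]] <- m
    ln <- ln + 2L + nb
  }
  if (f == 0L) stop("parse error: file contains no frames")
  coords <- array(0, c(nbExp, 3, f))
  for (k in seq_len(f)) coords[, , k] <- frames[[k]]
  ensemble(top, coords, time = times, boxEdge = boxes)
}

#' Write a conformational ensemble to disk
#'
#' PDB output is written in Angstrom (multi-model, `CRYST1` record when a
#' box is present); XYZ output in nm with `time=` and `box=` entries on the
#' comment line.
#'
#' @param x an [Ensemble].
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(x, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "pdb") writeEnsemblePDB(x, path) else writeEnsembleXYZ(x, path)
  invisible(path)
}

writeEnsemblePDB <- function(x, path) {
  top <- x@topology
  bn <- rep(beadNamesOf(top), top@nMolecules)
  lay <- beadLayout(top)
  resName <- rep(rep(top@residues$name, times = top@residues$nBeads), top@nMolecules)
  resSeq <- rep(rep(top@residues$index, times = top@residues$nBeads), top@nMolecules)
  chain <- LETTERS[(rep(seq_len(top@nMolecules),
                        each = beadsPerMolecule(top)) - 1L) %% 26 + 1L]
  con <- file(path, "w"); on.exit(close(con))
  L <- x@boxEdge[1]
  if (!is.na(L))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       L * 10, L * 10, L * 10), con)
  for (f in seq_len(nFrames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- x@coords[, , f] * 10  # nm -> A
    writeLines(sprintf("ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_along(bn), bn, resName, chain, resSeq,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

writeEnsembleXYZ <- function(x, path) {
  top <- x@topology
  bn <- rep(beadNamesOf(top), top@nMolecules)
  nb <- length(bn)
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nFrames(x))) {
    bx <- x@boxEdge[f]
    writeLines(as.character(nb), con)
    writeLines(sprintf("frame=%d time=%.8g%s", f, x@time[f],
                       if (is.na(bx)) "" else sprintf(" box=%.8g", bx)), con)
    xyz <- x@coords[, , f]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-4s %14.6f %14.6f %14.6f", bn,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
}

#' Read a 3-column SAXS curve (q, I, sigma)
#'
#' Whitespace-separated text with optional `#` comments. q must be strictly
#' increasing and the uncertainties positive.
#'
#' @param path file path.
#' @return a [ScatteringProfile] with uncertainties.
#' @export
readSAXSCurve <- function(path) {
  tb <- tryCatch(utils::read.table(path, comment.char = "#"),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  if (ncol(tb) < 3) stop("format error: expected 3 columns (q, I, sigma)")
  q <- tb[[1]]; I <- tb[[2]]; s <- tb[[3]]
  if (anyNA(q) || anyNA(I) || anyNA(s))
    stop("format error: non-numeric values in (q, I, sigma) columns")
  if (any(diff(q) <= 0)) stop("format error: q must be strictly increasing")
  if (any(s <= 0)) stop("format error: sigma must be positive")
  scatteringProfile(q, I, s)
}

#' Write a SAXS curve as 3-column text
#' @param x a [ScatteringProfile].
#' @param path output path.
#' @export
writeSAXSCurve <- function(x, path) {
  s <- if (length(x@sigma)) x@sigma else rep(NA_real_, length(x@q))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# q[nm^-1]  I(q)  sigma", con)
  writeLines(sprintf("%.10g %.10g %.10g", x@q, x@intensity, s), con)
  invisible(path)
}
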