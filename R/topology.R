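#' Construct a bead topology
#'
#' @param names character vector of 3-letter residue codes, in sequence order.
#' @param nBeads integer vector (recycled) of beads per residue.
#' @param backbone integer vector (recycled): which bead of each residue is
#'   the backbone bead.
#' @param domains named list of inclusive residue intervals `c(first, last)`;
#'   must be disjoint and cover the sequence. Defaults to a single domain
#'   `"ALL"` spanning the chain.
#' @param strands named list of inclusive residue intervals for beta strands
#'   (must lie within the `"CRD"` domain when one is declared).
#' @param nMolecules number of identical copies of the molecule.
#' @return a [BeadTopology].
#' @examples
#' top <- beadTopology(rep("GLY", 10), domains = list(ALL = c(1, 10)))
#' nResidues(top)
#' @export
beadTopology <- function(names, nBeads = 1L, backbone = 1L,
                         domains = NULL, strands = list(), nMolecules = 1L) {
  n <- length(names)
  if (is.null(domains)) domains <- list(ALL = c(1L, n))
  nBeads <- as.integer(rep_len(nBeads, n))
  backbone <- as.integer(rep_len(backbone, n))
  domLab <- rep(NA_character_, n)
  for (d in names(domains)) {
    iv <- domains[[d]]
    domLab[iv[1]:iv[2]] <- d
  }
  res <- data.frame(index = seq_len(n), name = toupper(as.character(names)),
                    nBeads = nBeads, backbone = backbone,
                    aromatic = toupper(names) %in% AROMATIC_NAMES,
                    domain = domLab, stringsAsFactors = FALSE)
  new("BeadTopology", residues = res,
      domains = lapply(domains, as.integer),
      strands = lapply(strands, as.integer),
      nMolecules = as.integer(nMolecules))
}

#' @rdname BeadTopology-class
#' @export
setMethod("nResidues", "BeadTopology", function(x) nrow(x@residues))

#' @rdname BeadTopology-class
#' @export
setMethod("nMolecules", "BeadTopology", function(x) x@nMolecules)

#' @rdname BeadTopology-class
#' @export
setMethod("domains", "BeadTopology", function(x) x@domains)

#' @rdname BeadTopology-class
#' @export
setMethod("strands", "BeadTopology", function(x) x@strands)

#' Number of beads in one molecule of a topology
#' @param x a [BeadTopology].
#' @export
beadsPerMolecule <- function(x) sum(x@residues$nBeads)

## 0-based global bead index of the first bead of each residue, across all
## molecules, plus companion lookup vectors used by the C++ kernels.
beadLayout <- function(top) {
  nb1 <- beadsPerMolecule(top)
  nres <- nResidues(top)
  start1 <- cumsum(c(0L, top@residues$nBeads))[seq_len(nres)]
  nm <- top@nMolecules
  list(
    beadStart = as.integer(rep(start1, nm) + rep((seq_len(nm) - 1L) * nb1, each = nres)),
    beadCount = rep(top@residues$nBeads, nm),
    backbone = as.integer(rep(start1 + top@residues$backbone - 1L, nm) +
                            rep((seq_len(nm) - 1L) * nb1, each = nres)),
    mol = rep(seq_len(nm) - 1L, each = nres),
    seq = rep(top@residues$index, nm),
    beadMol = rep(seq_len(nm) - 1L, each = nb1),
    beadsPerMol = nb1, nResMol = nres, nMol = nm
  )
}

#' Residue indices of one domain
#' @param x a [BeadTopology].
#' @param domain domain name.
#' @export
domainResidues <- function(x, domain) {
  iv <- x@domains[[domain]]
  if (is.null(iv)) stop("topology has no domain named '", domain, "'")
  iv[1]:iv[2]
}

#' Galectin-3 domain and beta-strand tables
#'
#' The full-length galectin-3 annotation used throughout the package: the
#' disordered N-terminal domain (NTD) spans residues 1-112, the carbohydrate
#' recognition domain (CRD) residues 113-250, and the eleven CRD beta strands
#' have the residue ranges beta1 = 118-121 ... beta11 = 240-249.
#'
#' @return list with elements `domains` and `strands` (named lists of
#'   inclusive residue intervals).
#' @examples
#' galectin3Domains()$domains
#' @export
galectin3Domains <- function() {
  list(
    domains = list(NTD = c(1L, 112L), CRD = c(113L, 250L)),
    strands = list(
      beta1 = c(118L, 121L), beta2 = c(130L, 138L), beta3 = c(145L, 151L),
      beta4 = c(154L, 162L), beta5 = c(170L, 174L), beta6 = c(185L, 187L),
      beta7 = c(197L, 204L), beta8 = c(208L, 213L), beta9 = c(216L, 222L),
      beta10 = c(233L, 238L), beta11 = c(240L, 249L))
  )
}

#' One-bead-per-residue galectin-3-like topology
#'
#' A 250-residue topology carrying the [galectin3Domains()] annotation, with
#' one bead per residue. Residue names default to `"GLY"` (the synthetic
#' generators carry no sequence); pass `names` to override.
#'
#' @param nMolecules number of identical molecules.
#' @param names optional residue names (length 250).
#' @export
galectin3Topology <- function(nMolecules = 1L, names = NULL) {
  g <- galectin3Domains()
  if (is.null(names)) names <- rep("GLY", 250)
  beadTopology(names, domains = g$domains, strands = g$strands,
               nMolecules = nMolecules)
}

#' Read or write a topology configuration (JSON)
#'
#' The JSON layout mirrors the class: `n_molecules`, a `residues` array with
#' `index`, `name`, `n_beads`, `backbone` per residue, and `domains` /
#' `strands` objects mapping names to inclusive `[first, last]` residue
#' intervals.
#'
#' @param path file path.
#' @return a [BeadTopology] (`readTopology`) or `path` invisibly.
#' @export
readTopology <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  res <- j$residues
  beadTopology(res$name, nBeads = res$n_beads, backbone = res$backbone,
               domains = lapply(j$domains, as.integer),
               strands = if (length(j$strands)) lapply(j$strands, as.integer) else list(),
               nMolecules = if (is.null(j$n_molecules)) 1L else as.integer(j$n_molecules))
}

#' @rdname readTopology
#' @param x a [BeadTopology] to write.
#' @export
writeTopology <- function(x, path) {
  j <- list(
    n_molecules = x@nMolecules,
    residues = data.frame(index = x@residues$index, name = x@residues$name,
                          n_beads = x@residues$nBeads,
                          backbone = x@residues$backbone),
    domains = x@domains, strands = x@strands)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "BeadTopology", function(object) {
  cat(sprintf("BeadTopology: %d residue(s) x %d molecule(s), %d bead(s)/molecule\n",
              nResidues(object), object@nMolecules, beadsPerMolecule(object)))
  if (length(object@domains))
    cat("  domains:", paste(sprintf("%s[%d-%d]", names(object@domains),
        vapply(object@domains, `[`, 1L, 1), vapply(object@domains, `[`, 1L, 2)),
        collapse = " "), "\n")
  if (length(object@strands))
    cat("  strands:", length(object@strands), "beta-strand range(s)\n")
})
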