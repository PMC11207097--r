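# Shared fixtures and independent oracles, built in code at test time.

B_KUHN <- 0.55  # nm

## tiny ensemble from an explicit list of [beads, 3] frame matrices
ensembleFromFrames <- function(top, frames, boxEdge = NA_real_) {
  arr <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  ensemble(top, arr, boxEdge = boxEdge)
}

## random rigid motion applied to every frame of an ensemble
applyRigidMotion <- function(ens, rot, shift) {
  arr <- ens@coords
  for (f in seq_len(dim(arr)[3]))
    arr[, , f] <- sweep(arr[, , f] %*% t(rot), 2, shift, "+")
  ensemble(topology(ens), arr, time = frameTimes(ens),
           boxEdge = boxEdges(ens))
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## brute-force residue contact oracle: double loop over bead pairs
oracleContacts <- function(xyz, top, cutoff = 0.7, nIgnore = 3,
                           inter = FALSE, L = NA) {
  res <- top@residues
  nres <- nrow(res)
  nm <- top@nMolecules
  nb1 <- sum(res$nBeads)
  beadRes <- rep(rep(seq_len(nres), times = res$nBeads), nm)
  beadMol <- rep(seq_len(nm), each = nb1)
  out <- NULL
  nbTot <- nrow(xyz)
  for (u in seq_len(nbTot - 1)) for (v in (u + 1):nbTot) {
    sameMol <- beadMol[u] == beadMol[v]
    if (inter && sameMol) next
    if (!inter && !sameMol) next
    i <- beadRes[u]; j <- beadRes[v]
    if (!inter && abs(i - j) <= nIgnore) next
    d <- xyz[u, ] - xyz[v, ]
    if (inter && !is.na(L)) d <- d - L * round(d / L)
    if (sqrt(sum(d^2)) < cutoff) {
      key <- c(beadMol[u], i, beadMol[v], j)
      if (key[1] > key[3] || (key[1] == key[3] && key[2] > key[4]))
        key <- key[c(3, 4, 1, 2)]
      out <- rbind(out, key)
    }
  }
  if (is.null(out)) return(data.frame(molI = integer(), i = integer(),
                                      molJ = integer(), j = integer()))
  out <- unique(as.data.frame(out))
  names(out) <- c("molI", "i", "molJ", "j")
  sortContacts(out)
}

sortContacts <- function(df) {
  df <- df[order(df$molI, df$i, df$molJ, df$j), ]
  rownames(df) <- NULL
  df
}

## union-find connected-components oracle over a molecule adjacency matrix
oracleComponents <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (adj[a, b]) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) {
        parent[ra] <- min(ra, rb)
        parent[rb] <- min(ra, rb)
      }
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## fitted Flory exponent of an ensemble, RMS backbone convention
fittedNu <- function(ens, bFree = TRUE) {
  sc <- scalingCurve(ens, mode = "rms", distance = "backbone")
  fitFlory(sc, bFixed = if (bFree) NA else B_KUHN)@nu
}
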