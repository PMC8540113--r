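# Independent oracles used by the property and acceptance tests.  These
# deliberately avoid the package's own computational paths.

# Brute-force first Zagreb index: explicit double loop over the adjacency
# matrix (row sums squared, element by element).
bruteZagreb <- function(m) {
  n <- heavyAtomCount(m)
  A <- matrix(0L, n, n)
  b <- bondList(m)
  for (r in seq_len(nrow(b))) {
    A[b[r, 1], b[r, 2]] <- 1L
    A[b[r, 2], b[r, 1]] <- 1L
  }
  z <- 0L
  for (i in seq_len(n)) {
    di <- 0L
    for (j in seq_len(n)) di <- di + A[i, j]
    z <- z + di * di
  }
  z
}

# Random connected molecule-like graph (random spanning tree plus extra
# edges); explicit hydrogens set to zero so arbitrary degrees are legal.
randomGraphMolecule <- function(nAtoms, nExtra = 2L) {
  atoms <- sample(c("C", "O"), nAtoms, replace = TRUE)
  bonds <- NULL
  if (nAtoms > 1L) {
    for (v in 2:nAtoms)
      bonds <- rbind(bonds, c(sample(v - 1L, 1L), v))
    tries <- 0L
    while (nExtra > 0L && tries < 50L) {
      cand <- sort(sample(nAtoms, 2L))
      key <- paste(pmin(bonds[, 1], bonds[, 2]),
                   pmax(bonds[, 1], bonds[, 2]))
      if (!(paste(cand[1], cand[2]) %in% key)) {
        bonds <- rbind(bonds, cand)
        nExtra <- nExtra - 1L
      }
      tries <- tries + 1L
    }
  } else {
    bonds <- matrix(integer(), ncol = 2L)
  }
  moleculeFromAdjacency(atoms, bonds, explicitH = rep(0L, nAtoms),
                        name = "random")
}

# Dense grid search for the Norrish constant: coarse pass over the whole
# bracket, fine pass around the coarse minimum.
gridSearchKn <- function(data, lo = -50, hi = 10,
                         coarse = 1e-2, fine = 1e-5) {
  ks <- seq(lo, hi, by = coarse)
  obj <- vapply(ks, norrishObjective, numeric(1), data = data)
  k0 <- ks[which.min(obj)]
  ks2 <- seq(max(lo, k0 - 2 * coarse), min(hi, k0 + 2 * coarse), by = fine)
  obj2 <- vapply(ks2, norrishObjective, numeric(1), data = data)
  ks2[which.min(obj2)]
}

# Grid-refinement least squares for a linear-in-parameter model:
# minimizes ||k - X p|| over a box around the running best grid point,
# shrinking each dimension unless the optimum sits on the box edge (then
# that dimension is expanded), which lets the search track correlated
# valleys.  Independent of lm()/normal equations.
gridRefineOLS <- function(X, k, lower, upper, nGrid = 21L, iters = 120L,
                          shrink = 0.5) {
  center <- (lower + upper) / 2
  half <- (upper - lower) / 2
  best <- center
  for (it in seq_len(iters)) {
    axes <- lapply(seq_along(center), function(j)
      seq(center[j] - half[j], center[j] + half[j], length.out = nGrid))
    grid <- as.matrix(expand.grid(axes))
    rss <- colSums((k - X %*% t(grid))^2)
    best <- grid[which.min(rss), ]
    for (j in seq_along(center)) {
      atEdge <- abs(best[j] - center[j]) >= half[j] * (1 - 1e-9)
      half[j] <- if (atEdge) half[j] * 2 else half[j] * shrink
    }
    center <- best
  }
  unname(best)
}

# Eight-solute reference data joined to full-precision computed
# descriptors (used by several tests).
referenceFitData <- function() {
  ref <- referenceNorrishConstants()
  d <- descriptorTable(lapply(ref$solute, builtinSolute))
  d$k_N <- ref$k_N[match(d$solute, ref$solute)]
  d
}
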