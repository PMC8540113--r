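# Molecular graph construction: SMILES subset parser, adjacency input,
# built-in solute library.  Only the H-depleted graph plus implicit
# hydrogen counts are retained; this is all the descriptors need.

# Valence registry.  Keyed by element symbol so further elements can be
# registered without code changes; implicit hydrogens on a heavy atom are
# standard valence minus heavy-atom degree.
.valences <- new.env(parent = emptyenv())
local({
  defaults <- c(C = 4L, O = 2L, N = 3L, S = 2L, P = 3L,
                F = 1L, Cl = 1L, Br = 1L, I = 1L)
  for (s in names(defaults)) assign(s, defaults[[s]], envir = .valences)
})

#' Standard valence registry
#'
#' The implicit-hydrogen rule assigns each heavy atom
#' `valence - degree` hydrogens.  `atomValences()` lists the registered
#' symbols; `registerValence()` adds or overrides one, so elements beyond
#' the default organic set can be supported without code changes.
#'
#' @param symbol element symbol (case-sensitive, e.g. `"N"`).
#' @param valence nonnegative integer standard valence.
#' @return `atomValences()` returns a named integer vector;
#'   `registerValence()` invisibly returns the new valence.
#' @examples
#' atomValences()
#' @export
atomValences <- function() {
  syms <- ls(.valences)
  setNames(vapply(syms, function(s) get(s, envir = .valences), integer(1)),
           syms)
}

#' @rdname atomValences
#' @export
registerValence <- function(symbol, valence) {
  stopifnot(is.character(symbol), length(symbol) == 1L,
            valence >= 0, valence == as.integer(valence))
  assign(symbol, as.integer(valence), envir = .valences)
  invisible(as.integer(valence))
}

.valenceOf <- function(symbol) {
  if (!exists(symbol, envir = .valences))
    stop(sprintf("no registered valence for atom symbol '%s'", symbol),
         call. = FALSE)
  get(symbol, envir = .valences)
}

.newMolecule <- function(name, atoms, bonds, hydrogens) {
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  new("Molecule", name = as.character(name), atoms = atoms,
      bonds = bonds, hydrogens = as.integer(hydrogens))
}

.degrees <- function(atoms, bonds) {
  d <- integer(length(atoms))
  if (nrow(bonds)) {
    t1 <- tabulate(bonds[, 1L], nbins = length(atoms))
    t2 <- tabulate(bonds[, 2L], nbins = length(atoms))
    d <- t1 + t2
  }
  d
}

# connected components by breadth-first search; returns component count
.nComponents <- function(nAtoms, bonds) {
  if (nAtoms == 0L) return(0L)
  adj <- vector("list", nAtoms)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1L]; j <- bonds[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(nAtoms)
  ncomp <- 0L
  for (start in seq_len(nAtoms)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Parse a SMILES string into a Molecule
#'
#' Supports the subset of SMILES needed for sugar and polyol skeletons:
#' uppercase element symbols with registered valences (see
#' [atomValences()]; two-letter symbols such as `Cl` are recognized),
#' branches `(`...`)`, explicit single bonds `-`, and single-digit ring
#' closures.  Stereo bond markers `/`, `\` and chirality marks `@` are
#' silently stripped with a warning — both descriptors computed downstream
#' are stereochemistry-blind, so e.g. the glucose/fructose distinction
#' comes from ring connectivity, not configuration.  Aromatic atoms,
#' charges, isotopes, multiple bonds and bracket atoms are rejected with an
#' error naming the offending character and its position.
#'
#' Implicit hydrogens are assigned per heavy atom as standard valence
#' minus heavy-atom degree; a negative count raises a valence error.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule label (defaults to the SMILES itself).
#' @return a [Molecule-class] object.
#' @examples
#' glycerol <- parseSmiles("OCC(O)CO", name = "glycerol")
#' formulaCounts(glycerol)   # C3 H8 O3
#' vertexDegrees(glycerol)
#' @export
parseSmiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1]]
  atoms <- character()
  hcap <- integer()          # valence cap per atom
  bonds <- matrix(integer(), ncol = 2L)
  prev <- NA_integer_        # atom the next atom bonds to
  stack <- integer()         # branch return points
  ringOpen <- list()         # digit -> atom index awaiting closure
  strippedStereo <- FALSE
  i <- 1L
  n <- length(chars)
  addBond <- function(a, b) {
    if (a == b)
      stop(sprintf("ring closure forms a self-loop at atom %d", a),
           call. = FALSE)
    bonds <<- rbind(bonds, c(a, b))
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("@", "/", "\\")) {          # stereo: strip
      strippedStereo <- TRUE
      i <- i + 1L
      next
    }
    if (ch == "-") { i <- i + 1L; next }       # explicit single bond
    if (ch == "(") {
      if (is.na(prev))
        stop(sprintf("branch opened before any atom at position %d", i),
             call. = FALSE)
      stack <- c(stack, prev)
      i <- i + 1L
      next
    }
    if (ch == ")") {
      if (!length(stack))
        stop(sprintf("unmatched ')' at position %d", i), call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
      next
    }
    if (grepl("^[1-9]$", ch)) {               # ring closure digit
      if (is.na(prev))
        stop(sprintf("ring-closure digit before any atom at position %d", i),
             call. = FALSE)
      if (!is.null(ringOpen[[ch]])) {
        addBond(ringOpen[[ch]], prev)
        ringOpen[[ch]] <- NULL
      } else {
        ringOpen[[ch]] <- prev
      }
      i <- i + 1L
      next
    }
    if (grepl("^[A-Z]$", ch)) {               # atom symbol (maybe 2-letter)
      sym <- ch
      if (i < n && grepl("^[a-z]$", chars[i + 1L]) &&
          exists(paste0(ch, chars[i + 1L]), envir = .valences)) {
        sym <- paste0(ch, chars[i + 1L])
        i <- i + 1L
      }
      val <- tryCatch(.valenceOf(sym), error = function(e)
        stop(sprintf("unsupported atom symbol '%s' at position %d", sym, i),
             call. = FALSE))
      atoms <- c(atoms, sym)
      hcap <- c(hcap, val)
      idx <- length(atoms)
      if (!is.na(prev)) addBond(prev, idx)
      prev <- idx
      i <- i + 1L
      next
    }
    stop(sprintf("unsupported SMILES token '%s' at position %d", ch, i),
         call. = FALSE)
  }
  if (length(stack))
    stop("unmatched '(' in SMILES", call. = FALSE)
  if (length(ringOpen))
    stop(sprintf("unmatched ring-closure digit(s): %s",
                 paste(names(ringOpen), collapse = ", ")), call. = FALSE)
  if (!length(atoms))
    stop("SMILES contains no atoms", call. = FALSE)
  if (strippedStereo)
    warning("stereo markers stripped from SMILES (descriptors are ",
            "stereochemistry-blind)", call. = FALSE)
  deg <- .degrees(atoms, bonds)
  hyd <- hcap - deg
  bad <- which(hyd < 0L)
  if (length(bad))
    stop(sprintf("valence error: atom %d (%s) has degree %d exceeding valence %d",
                 bad[1L], atoms[bad[1L]], deg[bad[1L]], hcap[bad[1L]]),
         call. = FALSE)
  .newMolecule(name, atoms, bonds, hyd)
}

#' Build a Molecule from an explicit adjacency list
#'
#' Alternative input path so hydrogen-depleted graphs can be entered
#' directly (e.g. transcribed from a drawn structure).  Hydrogens are
#' filled in by the valence rule unless `explicitH` is supplied.
#'
#' @param atoms character vector of element symbols (vertices).
#' @param bonds edges, either a list of length-2 integer vectors or a
#'   two-column matrix of 1-based vertex indices.
#' @param explicitH optional integer vector, one implicit-hydrogen count
#'   per vertex, overriding the valence rule.
#' @param name molecule label.
#' @return a [Molecule-class] object.
#' @examples
#' # xylitol as drawn: 5-carbon chain, one pendant oxygen per carbon
#' xyl <- moleculeFromAdjacency(
#'   atoms = c("C", "C", "C", "C", "C", "O", "O", "O", "O", "O"),
#'   bonds = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
#'                c(1, 6), c(2, 7), c(3, 8), c(4, 9), c(5, 10)),
#'   name = "xylitol")
#' firstZagrebIndex(xyl)    # 40
#' @export
moleculeFromAdjacency <- function(atoms, bonds, explicitH = NULL,
                                  name = "molecule") {
  if (!length(atoms))
    stop("empty molecule rejected: no atoms given", call. = FALSE)
  atoms <- as.character(atoms)
  if (is.list(bonds)) {
    bonds <- if (length(bonds))
      do.call(rbind, lapply(bonds, function(b) as.integer(b[1:2])))
    else matrix(integer(), ncol = 2L)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  nA <- length(atoms)
  if (nrow(bonds)) {
    if (any(!is.finite(bonds)) || any(bonds < 1L) || any(bonds > nA))
      stop("bond index out of range", call. = FALSE)
    if (any(bonds[, 1L] == bonds[, 2L]))
      stop("self-loop bond rejected", call. = FALSE)
    key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                 pmax(bonds[, 1L], bonds[, 2L]))
    if (anyDuplicated(key))
      stop("duplicate bond rejected", call. = FALSE)
  }
  deg <- .degrees(atoms, bonds)
  if (is.null(explicitH)) {
    hyd <- vapply(seq_len(nA),
                  function(i) .valenceOf(atoms[i]) - deg[i], integer(1))
    if (any(hyd < 0L))
      stop("valence error: vertex degree exceeds registered valence",
           call. = FALSE)
  } else {
    stopifnot(length(explicitH) == nA, all(explicitH >= 0))
    hyd <- as.integer(explicitH)
  }
  .newMolecule(name, atoms, bonds, hyd)
}

# Built-in solute SMILES.  The sugars are the cyclic hemiacetal forms
# (glucopyranose, fructofuranose, xylopyranose, and sucrose as
# glucopyranosyl-fructofuranoside): only these ring forms reproduce the
# reference first Zagreb indices (58, 60, 48, 120); open-chain forms do
# not.  Polyols are open chains.  Stereochemistry is omitted throughout:
# both descriptors are stereochemistry-blind.
.builtinSmiles <- c(
  glucose    = "OCC1OC(O)C(O)C(O)C1O",
  fructose   = "OCC1(O)C(O)C(O)C(CO)O1",
  xylose     = "OC1COC(O)C(O)C1O",
  sucrose    = "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
  sorbitol   = "OCC(O)C(O)C(O)C(O)CO",
  xylitol    = "OCC(O)C(O)C(O)CO",
  glycerol   = "OCC(O)CO",
  erythritol = "OCC(O)C(O)CO"
)

#' Built-in solute library
#'
#' The eight sugar and polyol solutes of the reference study, as the
#' structural forms whose descriptors reproduce the published reference
#' values: glucose as glucopyranose, fructose as fructofuranose, xylose as
#' xylopyranose, sucrose as the glycosidically linked
#' glucopyranosyl-fructofuranoside, and the four polyols (sorbitol,
#' xylitol, glycerol, erythritol) as open chains.
#'
#' @param name solute name, case-insensitive; one of
#'   `builtinSoluteNames()`.
#' @return `builtinSolute()` returns a [Molecule-class];
#'   `builtinSoluteNames()` the vector of recognized names;
#'   `builtinSoluteSmiles()` the named SMILES vector actually used.
#' @examples
#' glc <- builtinSolute("glucose")
#' heavyAtomCount(glc)   # 12
#' ringCount(glc)        # 1
#' countHydroxyls(glc)   # 5
#' @export
builtinSolute <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(trimws(name))
  if (!key %in% names(.builtinSmiles))
    stop(sprintf("unknown solute '%s'; valid names: %s", name,
                 paste(names(.builtinSmiles), collapse = ", ")),
         call. = FALSE)
  parseSmiles(.builtinSmiles[[key]], name = key)
}

#' @rdname builtinSolute
#' @export
builtinSoluteNames <- function() names(.builtinSmiles)

#' @rdname builtinSolute
#' @export
builtinSoluteSmiles <- function() .builtinSmiles

#' Count hydroxyl groups
#'
#' A hydroxyl group is an oxygen vertex of heavy-atom degree 1 carrying
#' exactly one implicit hydrogen.  The bare water molecule (`"O"`) has an
#' oxygen of degree 0 and therefore no hydroxyl group under this
#' definition.
#'
#' @param m a [Molecule-class].
#' @return nonnegative integer count.
#' @examples
#' countHydroxyls(builtinSolute("glycerol"))  # 3
#' @export
countHydroxyls <- function(m) {
  stopifnot(is(m, "Molecule"))
  deg <- vertexDegrees(m)
  sum(m@atoms == "O" & deg == 1L & m@hydrogens == 1L)
}

#' Read a tab-separated SMILES file
#'
#' One record per line, `name<TAB>smiles`.  Blank lines and lines starting
#' with `#` are skipped.  Parse failures are collected and reported with
#' the offending line number.
#'
#' @param path file path.
#' @return list of [Molecule-class] objects.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  out <- list()
  errs <- character()
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      errs <- c(errs, sprintf("line %d: expected name<TAB>smiles", ln))
      next
    }
    mol <- tryCatch(parseSmiles(trimws(fields[2]), name = trimws(fields[1])),
                    error = function(e)
                      conditionMessage(e))
    if (is.character(mol))
      errs <- c(errs, sprintf("line %d (%s): %s", ln, trimws(fields[1]), mol))
    else out[[length(out) + 1L]] <- mol
  }
  if (length(errs))
    stop("SMILES file errors:\n", paste(errs, collapse = "\n"), call. = FALSE)
  out
}

#' Read a molecule from an adjacency JSON file
#'
#' Expects `{"name": ..., "atoms": ["C", ...], "bonds": [[1,2], ...]}`
#' with 1-based vertex indices and optionally `"explicit_h"`.
#'
#' @param path file path.
#' @return a [Molecule-class].
#' @export
readAdjacencyJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  bonds <- obj$bonds
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2L)
  moleculeFromAdjacency(obj$atoms, bonds,
                        explicitH = obj$explicit_h,
                        name = if (is.null(obj$name)) "molecule" else obj$name)
}

# ---- Molecule methods --------------------------------------------------

#' Molecule accessors
#'
#' @param x a [Molecule-class].
#' @return `formulaCounts()` returns a named integer vector over all atoms
#'   including hydrogen (C first, then H, then remaining symbols
#'   alphabetically); `ringCount()` is the cyclomatic number
#'   (bonds - atoms + number of connected components); `vertexDegrees()`
#'   the heavy-atom degree of each vertex of the H-depleted graph.
#' @name Molecule-accessors
NULL

#' @rdname Molecule-accessors
#' @export
setMethod("moleculeName", "Molecule", function(x) x@name)

#' @rdname Molecule-accessors
#' @export
setMethod("heavyAtoms", "Molecule", function(x) x@atoms)

#' @rdname Molecule-accessors
#' @export
setMethod("bondList", "Molecule", function(x) x@bonds)

#' @rdname Molecule-accessors
#' @export
setMethod("hydrogenCounts", "Molecule", function(x) x@hydrogens)

#' @rdname Molecule-accessors
#' @export
setMethod("formulaCounts", "Molecule", function(x) {
  counts <- table(x@atoms)
  out <- setNames(as.integer(counts), names(counts))
  nH <- sum(x@hydrogens)
  if (nH > 0L) out <- c(out, H = nH)
  # Hill order: C then H then alphabetical; no carbon -> all alphabetical
  symbols <- names(out)
  ord <- if ("C" %in% symbols)
    c(intersect(c("C", "H"), symbols), sort(setdiff(symbols, c("C", "H"))))
  else sort(symbols)
  out[ord]
})

#' @rdname Molecule-accessors
#' @export
setMethod("heavyAtomCount", "Molecule", function(x) length(x@atoms))

#' @rdname Molecule-accessors
#' @export
setMethod("bondCount", "Molecule", function(x) nrow(x@bonds))

#' @rdname Molecule-accessors
#' @export
setMethod("ringCount", "Molecule", function(x)
  nrow(x@bonds) - length(x@atoms) + .nComponents(length(x@atoms), x@bonds))

#' @rdname Molecule-accessors
#' @export
setMethod("vertexDegrees", "Molecule", function(x)
  .degrees(x@atoms, x@bonds))

#' Molecular formula as a string
#'
#' @param m a [Molecule-class].
#' @return Hill-style formula string, e.g. `"C6H12O6"`.
#' @export
molecularFormula <- function(m) {
  fc <- formulaCounts(m)
  paste0(names(fc), ifelse(fc > 1L, fc, ""), collapse = "")
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %s | %d heavy atoms, %d bonds, %d ring(s)\n",
              object@name, molecularFormula(object),
              heavyAtomCount(object), bondCount(object),
              ringCount(object)))
  invisible(object)
})
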