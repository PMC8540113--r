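# Theoretical molecular descriptors: the information index on atomic
# composition (constitutional), the first Zagreb index (topological), and
# their sum, the global information index.

#' Information index on atomic composition (I_AC)
#'
#' Shannon-type constitutional descriptor computed over ALL atoms of the
#' molecule, hydrogens included:
#' \deqn{I_{AC} = A_{tot} \log_2 A_{tot} - \sum_j A_j \log_2 A_j,}
#' where \eqn{A_{tot}} is the total atom count and \eqn{A_j} the count of
#' atoms of element \eqn{j}.  For glucose (C6H12O6, \eqn{A_{tot} = 24})
#' this gives exactly 36 bits.  A molecule with a single atom type has
#' \eqn{I_{AC} = 0} (the limit of the formula, not an error).
#'
#' @param m a [Molecule-class].
#' @return \eqn{I_{AC}} in bits (nonnegative; full precision — round only
#'   for presentation).
#' @examples
#' informationIndexAC(builtinSolute("glucose"))   # 36
#' informationIndexAC(builtinSolute("glycerol"))  # 19.79...
#' @export
informationIndexAC <- function(m) {
  stopifnot(is(m, "Molecule"))
  counts <- formulaCounts(m)
  if (!length(counts) || any(counts < 1L))
    stop("empty composition", call. = FALSE)
  aTot <- sum(counts)
  aTot * log2(aTot) - sum(counts * log2(counts))
}

#' First Zagreb index (Z1)
#'
#' Sum of squared vertex degrees over the hydrogen-depleted molecular
#' graph:
#' \deqn{Z_1 = \sum_{i=1}^{V} \delta_i^2.}
#' Measures the degree of atomic branching; unlike \eqn{I_{AC}} it
#' discriminates constitutional isomers such as glucopyranose
#' (\eqn{Z_1 = 58}) and fructofuranose (\eqn{Z_1 = 60}).
#'
#' @param m a [Molecule-class] with at least one heavy atom.
#' @return nonnegative integer.
#' @examples
#' firstZagrebIndex(builtinSolute("xylitol"))  # 40
#' firstZagrebIndex(builtinSolute("sucrose"))  # 120
#' @export
firstZagrebIndex <- function(m) {
  stopifnot(is(m, "Molecule"))
  d <- vertexDegrees(m)
  sum(d * d)   # stays integer
}

#' Global information index (G)
#'
#' The combined descriptor \eqn{G = I_{AC} + Z_1}: atomic composition and
#' molecular connectivity folded into a single index.
#'
#' @param m a [Molecule-class].
#' @return dimensionless value, exactly
#'   `informationIndexAC(m) + firstZagrebIndex(m)`.
#' @examples
#' globalInformationIndex(builtinSolute("fructose"))  # 96
#' @export
globalInformationIndex <- function(m) {
  informationIndexAC(m) + firstZagrebIndex(m)
}

#' Descriptor table for a set of molecules
#'
#' Batch computation of all three indices plus the hydroxyl count, one row
#' per molecule, input order preserved.  Per-molecule failures are
#' reported with the molecule name attached.
#'
#' @param molecules list of [Molecule-class] objects (possibly empty).
#' @return `data.frame` with columns `solute`, `I_AC`, `Z1`, `G`, `n_OH`.
#' @examples
#' descriptorTable(lapply(builtinSoluteNames(), builtinSolute))
#' @export
descriptorTable <- function(molecules) {
  stopifnot(is.list(molecules))
  rows <- lapply(molecules, function(m) {
    res <- tryCatch(
      data.frame(solute = moleculeName(m),
                 I_AC = informationIndexAC(m),
                 Z1 = firstZagrebIndex(m),
                 G = globalInformationIndex(m),
                 n_OH = countHydroxyls(m),
                 stringsAsFactors = FALSE),
      error = function(e)
        stop(sprintf("descriptor computation failed for '%s': %s",
                     moleculeName(m), conditionMessage(e)), call. = FALSE))
    res
  })
  if (!length(rows))
    return(data.frame(solute = character(), I_AC = numeric(),
                      Z1 = integer(), G = numeric(), n_OH = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a descriptor table to CSV
#'
#' Columns `solute, I_AC, Z1, G, n_OH`; indices are written rounded to two
#' decimals (presentation precision), `Z1` and `n_OH` as integers.
#'
#' @param tab data.frame from [descriptorTable()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDescriptorTable <- function(tab, path) {
  out <- tab
  out$I_AC <- round(out$I_AC, 2)
  out$G <- round(out$G, 2)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
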