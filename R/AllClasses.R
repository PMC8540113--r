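#' Molecule: composition plus hydrogen-depleted graph
#'
#' A `Molecule` stores what the descriptors need and nothing more: the
#' heavy-atom (hydrogen-depleted) graph — vertices are non-hydrogen atoms,
#' edges are covalent bonds — together with the implicit hydrogen count of
#' each heavy atom, so that the full molecular formula is recoverable.
#' Vertex order is the input order; all descriptors computed from a
#' `Molecule` are invariant under vertex relabeling.
#'
#' @slot name single character label.
#' @slot atoms character vector of element symbols, one per heavy atom
#'   (graph vertex).
#' @slot bonds integer matrix with two columns; each row is an unordered
#'   pair of 1-based vertex indices (an edge of the H-depleted graph).
#' @slot hydrogens integer vector, implicit hydrogens attached to each
#'   heavy atom.
#'
#' @seealso [parseSmiles()], [moleculeFromAdjacency()], [builtinSolute()],
#'   [heavyAtomCount()], [vertexDegrees()], [formulaCounts()]
#' @exportClass Molecule
setClass("Molecule",
  representation(
    name = "character",
    atoms = "character",
    bonds = "matrix",
    hydrogens = "integer"
  ),
  prototype(
    name = NA_character_,
    atoms = character(),
    bonds = matrix(integer(), ncol = 2L),
    hydrogens = integer()
  )
)

setValidity("Molecule", function(object) {
  msg <- character()
  n <- length(object@atoms)
  b <- object@bonds
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (n < 1L)
    msg <- c(msg, "a Molecule must contain at least one heavy atom")
  if (ncol(b) != 2L)
    msg <- c(msg, "'bonds' must have two columns")
  else if (nrow(b) > 0L) {
    if (any(b < 1L) || any(b > n))
      msg <- c(msg, "bond indices out of range")
    else {
      if (any(b[, 1L] == b[, 2L]))
        msg <- c(msg, "self-loop bond found")
      key <- paste(pmin(b[, 1L], b[, 2L]), pmax(b[, 1L], b[, 2L]))
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate bond found")
    }
  }
  if (length(object@hydrogens) != n)
    msg <- c(msg, "'hydrogens' must have one entry per heavy atom")
  else if (any(object@hydrogens < 0L))
    msg <- c(msg, "negative implicit hydrogen count (valence error)")
  if (length(msg)) msg else TRUE
})

#' ActivityDataset: paired composition / water-activity observations
#'
#' Observations \eqn{(x_s, a_w)} for one binary aqueous system.  The water
#' mole fraction is implicit (\eqn{x_w = 1 - x_s}).  Validity enforces the
#' physical bounds \eqn{0 < x_s < 1} and \eqn{0 < a_w \le 1}; activity
#' values above 1 are rejected rather than clipped.
#'
#' @slot solute single character label.
#' @slot xs numeric vector of solute mole fractions.
#' @slot aw numeric vector of water activities, same length as `xs`.
#'
#' @seealso [activityDataset()], [fitNorrish()], [generateActivityDataset()]
#' @exportClass ActivityDataset
setClass("ActivityDataset",
  representation(solute = "character", xs = "numeric", aw = "numeric"),
  prototype(solute = NA_character_, xs = numeric(), aw = numeric())
)

setValidity("ActivityDataset", function(object) {
  msg <- character()
  if (length(object@solute) != 1L)
    msg <- c(msg, "'solute' must be a single string")
  if (length(object@xs) != length(object@aw))
    msg <- c(msg, "'xs' and 'aw' must have equal length")
  if (!all(is.finite(object@xs)) || !all(is.finite(object@aw)))
    msg <- c(msg, "non-finite values in activity data")
  else {
    if (any(object@xs <= 0) || any(object@xs >= 1))
      msg <- c(msg, "solute mole fractions must lie strictly inside (0, 1)")
    if (any(object@aw <= 0) || any(object@aw > 1))
      msg <- c(msg, "water activities must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' NorrishFit: estimated Norrish constant for one dataset
#'
#' Result of [fitNorrish()]: the Norrish constant minimizing the sum of
#' squared activity residuals, with the attained objective
#' \eqn{\Phi_{min}} and the mean absolute error \eqn{\varepsilon}.
#' `atBoundary` flags a minimizer that landed on the search interval
#' boundary (the fit should then be repeated with wider bounds).
#'
#' @slot solute label copied from the dataset.
#' @slot kn fitted Norrish constant (dimensionless).
#' @slot phiMin minimized objective, sum of squared residuals in
#'   water-activity units squared.
#' @slot epsilon mean absolute residual in water-activity units.
#' @slot n number of data points.
#' @slot atBoundary logical flag.
#'
#' @seealso [fitNorrish()], [norrishConstant()], [phiMin()], [epsilon()]
#' @exportClass NorrishFit
setClass("NorrishFit",
  representation(
    solute = "character", kn = "numeric", phiMin = "numeric",
    epsilon = "numeric", n = "integer", atBoundary = "logical"
  )
)

setValidity("NorrishFit", function(object) {
  msg <- character()
  if (object@phiMin < 0 || object@epsilon < 0)
    msg <- c(msg, "phiMin and epsilon must be nonnegative")
  # Cauchy-Schwarz: n * epsilon^2 <= Phi
  if (object@n * object@epsilon^2 > object@phiMin * (1 + 1e-8) + 1e-300)
    msg <- c(msg, "inconsistent fit summary: n * epsilon^2 > phiMin")
  if (length(msg)) msg else TRUE
})

#' QsprFit: a fitted structure-property model for the Norrish constant
#'
#' One of the five model forms linking \eqn{k_N} to the descriptors,
#' with its least-squares parameters, the sum of squared errors
#' \eqn{\Theta} (always in \eqn{k_N} space) and the variance statistic
#' \eqn{\varphi = \Theta / (n - p)} used for model comparison.
#'
#' @slot formId one of `"linear2"`, `"power2"`, `"linearG"`, `"powerG"`,
#'   `"polyG"`.
#' @slot params named numeric parameter vector (names as in [qsprForms()]).
#' @slot theta sum of squared \eqn{k_N} residuals.
#' @slot phi theta / (n - p).
#' @slot n number of solutes used in the fit.
#' @slot p number of model parameters.
#'
#' @seealso [fitQspr()], [evaluateModel()], [selectModel()], [modelVariance()]
#' @exportClass QsprFit
setClass("QsprFit",
  representation(
    formId = "character", params = "numeric", theta = "numeric",
    phi = "numeric", n = "integer", p = "integer"
  )
)

setValidity("QsprFit", function(object) {
  msg <- character()
  if (!object@formId %in% qsprFormIds())
    msg <- c(msg, sprintf("unknown form id '%s'", object@formId))
  else {
    want <- qsprForms()[[object@formId]]$params
    if (!identical(names(object@params), want))
      msg <- c(msg, sprintf("params must be named %s",
                            paste(want, collapse = ", ")))
    if (object@p != length(want))
      msg <- c(msg, "'p' does not match the model form")
  }
  if (object@theta < 0) msg <- c(msg, "theta must be nonnegative")
  if (object@n <= object@p)
    msg <- c(msg, "n must exceed the number of parameters")
  if (abs(object@phi - object@theta / (object@n - object@p)) >
      1e-12 * max(1, abs(object@phi)))
    msg <- c(msg, "phi must equal theta / (n - p)")
  if (length(msg)) msg else TRUE
})
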