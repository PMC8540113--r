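# Synthetic activity-data generation and the packaged literature
# reference values for the eight sugar/polyol solutes.

#' Generate a synthetic activity dataset
#'
#' Emulates an experimental water-activity series for a binary solution:
#' `nPoints` solute mole fractions spaced over `xsRange` (evenly, or
#' evenly in log space), Norrish-model activities for `knTrue`, plus
#' additive homoscedastic Gaussian noise of standard deviation
#' `noiseSigma` on \eqn{a_w}, clipped to (0, 1].  The default
#' `noiseSigma = 1e-3` matches the magnitude of the mean absolute errors
#' reported for real sugar/polyol datasets (about 3e-4 to 1.4e-3).
#' Reproducible: the RNG state is seeded locally from `seed` and the
#' caller's RNG state is left untouched.
#'
#' @param knTrue true Norrish constant.
#' @param xsRange length-2 range of solute mole fractions, inside (0, 1).
#' @param nPoints number of points (>= 2), default 10 (a typical
#'   experimental series length; the generator does not model any
#'   instrument-specific design).
#' @param noiseSigma Gaussian noise standard deviation on \eqn{a_w}
#'   (>= 0).
#' @param seed integer seed.
#' @param solute dataset label.
#' @param spacing `"linear"` (default) or `"log"` grid spacing.
#' @return an [ActivityDataset-class].
#' @examples
#' d <- generateActivityDataset(-2.920, c(0.023, 0.111), nPoints = 8,
#'                              noiseSigma = 0, seed = 1)
#' norrishConstant(fitNorrish(d))   # exactly -2.920
#' @export
generateActivityDataset <- function(knTrue, xsRange, nPoints = 10L,
                                    noiseSigma = 1e-3, seed = 1L,
                                    solute = "synthetic",
                                    spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  stopifnot(is.numeric(knTrue), length(knTrue) == 1L, is.finite(knTrue),
            length(xsRange) == 2L, all(is.finite(xsRange)))
  if (xsRange[1] <= 0 || xsRange[2] >= 1 || xsRange[1] > xsRange[2])
    stop("'xsRange' must lie inside (0, 1) with min <= max", call. = FALSE)
  if (nPoints < 2L) stop("'nPoints' must be at least 2", call. = FALSE)
  if (noiseSigma < 0) stop("'noiseSigma' must be nonnegative", call. = FALSE)
  xs <- if (spacing == "linear")
    seq(xsRange[1], xsRange[2], length.out = as.integer(nPoints))
  else
    exp(seq(log(xsRange[1]), log(xsRange[2]),
            length.out = as.integer(nPoints)))
  aw <- waterActivity(xs, knTrue)
  if (noiseSigma > 0) {
    noise <- withr_seed_rnorm(as.integer(seed), length(xs), noiseSigma)
    aw <- aw + noise
  }
  aw <- pmin(pmax(aw, .Machine$double.eps), 1)
  activityDataset(xs, aw, solute = solute)
}

# Draw Gaussian noise under a local RNG state so the caller's stream is
# not disturbed.
withr_seed_rnorm <- function(seed, n, sigma) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, mean = 0, sd = sigma)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "watact")
  if (!nzchar(path))
    stop(sprintf("packaged data file '%s' not found", file), call. = FALSE)
  path
}

#' Literature reference values for the eight solutes
#'
#' Machine-readable copies of the published reference tables for the
#' eight sugar/polyol systems, shipped so every stage of the pipeline is
#' testable offline:
#' \describe{
#'   \item{`referenceNorrishConstants()`}{per-solute experimental mole
#'     fraction range (`xs_min`, `xs_max`), fitted Norrish constant
#'     `k_N`, attained objective `phi_min` and mean absolute error
#'     `epsilon`.}
#'   \item{`referenceSoluteProperties()`}{molecular formula, molecular
#'     weight (g/mol), number of non-hydrogen atoms `n_heavy`, total bond
#'     count `n_bonds` (hydrogens included) and ring count `n_rings`.}
#'   \item{`referenceDescriptors()`}{`I_AC`, `Z1` and `G` as published
#'     (indices rounded to two decimals).}
#' }
#'
#' @return a `data.frame`, one row per solute.
#' @examples
#' referenceNorrishConstants()[, c("solute", "k_N")]
#' @export
referenceNorrishConstants <- function() {
  read.csv(.extdata("norrish_constants.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' @rdname referenceNorrishConstants
#' @export
referenceSoluteProperties <- function() {
  read.csv(.extdata("solute_properties.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

#' @rdname referenceNorrishConstants
#' @export
referenceDescriptors <- function() {
  read.csv(.extdata("descriptor_reference.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}
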