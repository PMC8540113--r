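# The Norrish water-activity model: forward evaluation, least-squares
# estimation of the Norrish constant, error metrics, curve generation and
# composition conversion.

#' Construct an activity dataset
#'
#' @param xs numeric vector of solute mole fractions, each in (0, 1).
#' @param aw numeric vector of water activities, each in (0, 1].
#' @param solute label.
#' @return an [ActivityDataset-class].
#' @examples
#' activityDataset(c(0.02, 0.05, 0.08), c(0.979, 0.944, 0.905), "demo")
#' @export
activityDataset <- function(xs, aw, solute = "unknown") {
  new("ActivityDataset", solute = as.character(solute),
      xs = as.numeric(xs), aw = as.numeric(aw))
}

#' @rdname ActivityDataset-accessors
#' @name ActivityDataset-accessors
#' @param x an [ActivityDataset-class].
NULL

#' @rdname ActivityDataset-accessors
#' @export
setMethod("soluteName", "ActivityDataset", function(x) x@solute)

#' @rdname ActivityDataset-accessors
#' @export
setMethod("moleFractions", "ActivityDataset", function(x) x@xs)

#' @rdname ActivityDataset-accessors
#' @export
setMethod("waterActivities", "ActivityDataset", function(x) x@aw)

#' @rdname ActivityDataset-accessors
#' @export
setMethod("nPoints", "ActivityDataset", function(x) length(x@xs))

setMethod("show", "ActivityDataset", function(object) {
  cat(sprintf("ActivityDataset '%s': %d points, x_s in [%.4g, %.4g]\n",
              object@solute, length(object@xs),
              if (length(object@xs)) min(object@xs) else NA,
              if (length(object@xs)) max(object@xs) else NA))
  invisible(object)
})

#' Norrish model water activity
#'
#' Forward evaluation of the one-parameter Norrish model for a binary
#' solution:
#' \deqn{a_w = x_w e^{k_N x_s^2} = (1 - x_s)\, e^{k_N x_s^2}.}
#' \eqn{k_N = 0} gives the Raoult (ideal) line \eqn{a_w = x_w}.
#'
#' @param xs solute mole fraction(s) in `[0, 1)` (vectorized).
#' @param kn Norrish constant.
#' @return water activity value(s).
#' @examples
#' waterActivity(0.1, 0)        # 0.9 (Raoult)
#' waterActivity(0.1, -2.920)   # glucose-like: 0.87410
#' @export
waterActivity <- function(xs, kn) {
  if (any(!is.finite(xs)) || any(xs < 0) || any(xs >= 1))
    stop("solute mole fraction must lie in [0, 1)", call. = FALSE)
  stopifnot(is.numeric(kn), length(kn) == 1L, is.finite(kn))
  (1 - xs) * exp(kn * xs^2)
}

#' Least-squares objective for the Norrish constant
#'
#' Sum of squared residuals between observed activities and Norrish-model
#' predictions:
#' \deqn{\Phi(k_N) = \sum_i (a_{w,i}^{exp} - a_{w,i}^{calc})^2.}
#'
#' @param kn candidate Norrish constant.
#' @param data an [ActivityDataset-class] with at least one point.
#' @return \eqn{\Phi(k_N)}.
#' @export
norrishObjective <- function(kn, data) {
  stopifnot(is(data, "ActivityDataset"))
  if (nPoints(data) == 0L) stop("empty dataset", call. = FALSE)
  sum((waterActivities(data) - waterActivity(moleFractions(data), kn))^2)
}

#' Mean absolute error of a Norrish fit
#'
#' \deqn{\varepsilon = \frac{1}{n}\sum_i |a_{w,i}^{exp} - a_{w,i}^{calc}|.}
#'
#' @param fit a [NorrishFit-class], or a bare numeric \eqn{k_N}.
#' @param data an [ActivityDataset-class].
#' @return mean absolute residual in water-activity units.
#' @export
meanAbsoluteError <- function(fit, data) {
  stopifnot(is(data, "ActivityDataset"))
  if (nPoints(data) == 0L) stop("empty dataset", call. = FALSE)
  kn <- if (is(fit, "NorrishFit")) norrishConstant(fit) else as.numeric(fit)
  mean(abs(waterActivities(data) - waterActivity(moleFractions(data), kn)))
}

#' Estimate the Norrish constant from activity data
#'
#' Minimizes \eqn{\Phi(k_N)} (see [norrishObjective()]) over a bounded
#' interval by derivative-free scalar minimization
#' (golden-section/parabolic interpolation via [stats::optimize()]).
#' The fit is performed in \eqn{a_w} space, exactly on the stated
#' objective — not on the linearization
#' \eqn{\ln(a_w/x_w) = k_N x_s^2}, which is used internally only as a
#' starting sanity value.  The default bracket `[-50, 10]` covers the
#' sugar/polyol range (roughly \eqn{-6.8} to \eqn{-0.9}) with wide margin.
#'
#' @param data an [ActivityDataset-class] with at least two points.
#' @param bounds length-2 numeric search interval for \eqn{k_N}.
#' @param tol absolute tolerance on \eqn{k_N} passed to the minimizer.
#' @return a [NorrishFit-class].  If the minimizer lands within `1e-6` of
#'   a bound, `atBoundary(fit)` is `TRUE` and a warning is emitted.
#' @examples
#' d <- generateActivityDataset(knTrue = -6.777, xsRange = c(0.018, 0.098),
#'                              nPoints = 10, noiseSigma = 0, seed = 1)
#' norrishConstant(fitNorrish(d))   # -6.777 recovered
#' @export
fitNorrish <- function(data, bounds = c(-50, 10), tol = 1e-10) {
  stopifnot(is(data, "ActivityDataset"))
  if (nPoints(data) < 2L)
    stop("at least two data points are required to fit the Norrish constant",
         call. = FALSE)
  stopifnot(length(bounds) == 2L, all(is.finite(bounds)),
            bounds[1] < bounds[2])
  opt <- optimize(norrishObjective, interval = bounds, data = data,
                  tol = tol)
  kn <- opt$minimum
  # optimize() stops short of the interval ends by O(tol + eps*|x|)
  boundary <- min(kn - bounds[1], bounds[2] - kn) <
    max(1e-6, 1e-6 * (bounds[2] - bounds[1]))
  if (boundary)
    warning("Norrish minimizer at search-interval boundary; widen 'bounds'",
            call. = FALSE)
  new("NorrishFit", solute = soluteName(data), kn = kn,
      phiMin = opt$objective,
      epsilon = meanAbsoluteError(kn, data),
      n = nPoints(data), atBoundary = boundary)
}

#' @rdname NorrishFit-accessors
#' @name NorrishFit-accessors
#' @param x a [NorrishFit-class].
NULL

#' @rdname NorrishFit-accessors
#' @export
setMethod("norrishConstant", "NorrishFit", function(x) x@kn)

#' @rdname NorrishFit-accessors
#' @export
setMethod("phiMin", "NorrishFit", function(x) x@phiMin)

#' @rdname NorrishFit-accessors
#' @export
setMethod("epsilon", "NorrishFit", function(x) x@epsilon)

#' @rdname NorrishFit-accessors
#' @export
setMethod("nPoints", "NorrishFit", function(x) x@n)

#' @rdname NorrishFit-accessors
#' @export
setMethod("atBoundary", "NorrishFit", function(x) x@atBoundary)

#' @rdname NorrishFit-accessors
#' @export
setMethod("soluteName", "NorrishFit", function(x) x@solute)

setMethod("show", "NorrishFit", function(object) {
  cat(sprintf(
    "NorrishFit '%s': k_N = %.4f, Phi_min = %.3e, epsilon = %.3e (n = %d)%s\n",
    object@solute, object@kn, object@phiMin, object@epsilon, object@n,
    if (object@atBoundary) " [at boundary]" else ""))
  invisible(object)
})

#' Water-activity curve for a given Norrish constant
#'
#' Evenly spaced grid from \eqn{x_s = 0} (pure water, \eqn{a_w = 1}) to
#' `xsMax`, with Norrish-model activities.
#'
#' @param kn Norrish constant.
#' @param xsMax largest solute mole fraction, in (0, 1).
#' @param nPoints number of grid points (>= 2).
#' @return `data.frame` with columns `x_s`, `a_w`; first row is `(0, 1)`.
#' @examples
#' activityCurve(0, xsMax = 0.5, nPoints = 3)  # Raoult line
#' @export
activityCurve <- function(kn, xsMax, nPoints = 101L) {
  stopifnot(is.numeric(xsMax), length(xsMax) == 1L)
  if (!is.finite(xsMax) || xsMax <= 0 || xsMax >= 1)
    stop("'xsMax' must lie in (0, 1)", call. = FALSE)
  if (!is.finite(nPoints) || nPoints < 2L)
    stop("'nPoints' must be at least 2", call. = FALSE)
  xs <- seq(0, xsMax, length.out = as.integer(nPoints))
  data.frame(x_s = xs, a_w = waterActivity(xs, kn))
}

#' Mole fraction from mass fraction
#'
#' Converts a solute mass fraction to a mole fraction for a binary aqueous
#' solution:
#' \deqn{x_s = \frac{w_s / MW_s}{w_s / MW_s + (1 - w_s) / MW_w}.}
#'
#' @param ws solute mass fraction(s) in `[0, 1)`.
#' @param mwSolute solute molecular weight, g/mol.
#' @param mwWater water molecular weight, g/mol (default 18.015).
#' @return solute mole fraction(s).
#' @examples
#' moleFractionFromMassFraction(0.5, 342.34)  # 50 wt% sucrose -> 0.05001
#' @export
moleFractionFromMassFraction <- function(ws, mwSolute, mwWater = 18.015) {
  if (any(!is.finite(ws)) || any(ws < 0) || any(ws >= 1))
    stop("mass fraction must lie in [0, 1)", call. = FALSE)
  stopifnot(mwSolute > 0, mwWater > 0)
  ns <- ws / mwSolute
  nw <- (1 - ws) / mwWater
  ns / (ns + nw)
}

#' Read / write activity data CSV
#'
#' Dialect: header `x_s,a_w`, decimal points (locale-independent), and an
#' optional leading comment line `# solute: <name>`.  Additional `#`
#' comment lines are ignored on read.
#'
#' @param path file path.
#' @param data an [ActivityDataset-class] (for writing).
#' @param comments extra comment lines to prepend (e.g. a generator seed).
#' @return `readActivityCsv()` returns an [ActivityDataset-class];
#'   `writeActivityCsv()` the path, invisibly.
#' @export
readActivityCsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  solute <- "unknown"
  cm <- grep("^#", lines, value = TRUE)
  sl <- grep("^#\\s*solute:", cm, value = TRUE)
  if (length(sl))
    solute <- trimws(sub("^#\\s*solute:", "", sl[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("x_s", "a_w")
  if (!all(need %in% names(tab)))
    stop("activity CSV must have columns 'x_s' and 'a_w'", call. = FALSE)
  activityDataset(tab$x_s, tab$a_w, solute = solute)
}

#' @rdname readActivityCsv
#' @export
writeActivityCsv <- function(data, path, comments = character()) {
  stopifnot(is(data, "ActivityDataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# solute: %s", soluteName(data)),
               if (length(comments)) paste0("# ", comments)), con)
  write.csv(data.frame(x_s = moleFractions(data),
                       a_w = waterActivities(data)),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
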