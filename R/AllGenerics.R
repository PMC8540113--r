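# Accessor generics.  Slot access from user code is discouraged; these are
# the supported surface.

#' @rdname Molecule-accessors
#' @export
setGeneric("moleculeName", function(x) standardGeneric("moleculeName"))

#' @rdname Molecule-accessors
#' @export
setGeneric("heavyAtoms", function(x) standardGeneric("heavyAtoms"))

#' @rdname Molecule-accessors
#' @export
setGeneric("bondList", function(x) standardGeneric("bondList"))

#' @rdname Molecule-accessors
#' @export
setGeneric("hydrogenCounts", function(x) standardGeneric("hydrogenCounts"))

#' @rdname Molecule-accessors
#' @export
setGeneric("formulaCounts", function(x) standardGeneric("formulaCounts"))

#' @rdname Molecule-accessors
#' @export
setGeneric("heavyAtomCount", function(x) standardGeneric("heavyAtomCount"))

#' @rdname Molecule-accessors
#' @export
setGeneric("bondCount", function(x) standardGeneric("bondCount"))

#' @rdname Molecule-accessors
#' @export
setGeneric("ringCount", function(x) standardGeneric("ringCount"))

#' @rdname Molecule-accessors
#' @export
setGeneric("vertexDegrees", function(x) standardGeneric("vertexDegrees"))

#' @rdname ActivityDataset-accessors
#' @export
setGeneric("soluteName", function(x) standardGeneric("soluteName"))

#' @rdname ActivityDataset-accessors
#' @export
setGeneric("moleFractions", function(x) standardGeneric("moleFractions"))

#' @rdname ActivityDataset-accessors
#' @export
setGeneric("waterActivities", function(x) standardGeneric("waterActivities"))

#' @rdname ActivityDataset-accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname NorrishFit-accessors
#' @export
setGeneric("norrishConstant", function(x) standardGeneric("norrishConstant"))

#' @rdname NorrishFit-accessors
#' @export
setGeneric("phiMin", function(x) standardGeneric("phiMin"))

#' @rdname NorrishFit-accessors
#' @export
setGeneric("epsilon", function(x) standardGeneric("epsilon"))

#' @rdname NorrishFit-accessors
#' @export
setGeneric("atBoundary", function(x) standardGeneric("atBoundary"))

#' @rdname QsprFit-accessors
#' @export
setGeneric("formId", function(x) standardGeneric("formId"))

#' @rdname QsprFit-accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname QsprFit-accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname QsprFit-accessors
#' @export
setGeneric("phi", function(x) standardGeneric("phi"))
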