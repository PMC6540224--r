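#' @rdname ScoreTable-accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("scoreNames", function(x) standardGeneric("scoreNames"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("propertyMatrix", function(x) standardGeneric("propertyMatrix"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("nActives", function(x) standardGeneric("nActives"))

#' @rdname ConsensusModel-accessors
#' @export
setGeneric("modelSubset", function(x) standardGeneric("modelSubset"))

#' @rdname ConsensusModel-accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname ConsensusModel-accessors
#' @export
setGeneric("trainQuality", function(x) standardGeneric("trainQuality"))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("selectedSubset", function(x) standardGeneric("selectedSubset"))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("finalModel", function(x) standardGeneric("finalModel"))

#' @rdname ValidationReport-accessors
#' @export
setGeneric("validationAverages", function(x) standardGeneric("validationAverages"))
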