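#' Accessors for workload containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @param ... passed to methods.
#' @return `fwfPlayer` the player identifier; `fwfValues` the numeric matrix
#'   or array of values; `fwfVariables` the variable names; `eventIndices`
#'   the 0-based event indices; `windowSizes` the tau window set;
#'   `featureMatrix`, `featureLabels`, `sampleInfo`, `variantSpec` the
#'   corresponding [FeatureTable-class] parts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fwfPlayer", function(x) standardGeneric("fwfPlayer"))

#' @rdname accessors
#' @export
setGeneric("fwfValues", function(x) standardGeneric("fwfValues"))

#' @rdname accessors
#' @export
setGeneric("fwfVariables", function(x) standardGeneric("fwfVariables"))

#' @rdname accessors
#' @export
setGeneric("eventIndices", function(x) standardGeneric("eventIndices"))

#' @rdname accessors
#' @export
setGeneric("windowSizes", function(x) standardGeneric("windowSizes"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("variantSpec", function(x) standardGeneric("variantSpec"))

#' @rdname accessors
#' @export
setGeneric("injuryLabels", function(x) standardGeneric("injuryLabels"))

#' @rdname accessors
#' @export
setGeneric("seasonCalendar", function(x) standardGeneric("seasonCalendar"))

#' @rdname accessors
#' @export
setGeneric("seasonRecords", function(x) standardGeneric("seasonRecords"))

#' @rdname accessors
#' @export
setGeneric("seasonRoster", function(x) standardGeneric("seasonRoster"))

#' @rdname accessors
#' @export
setGeneric("seasonInjuries", function(x) standardGeneric("seasonInjuries"))

#' Look up one cell of a cumulative or temporal variation block
#'
#' @param x a [TFWFMatrix-class].
#' @param variable variable name.
#' @param event 0-based event index.
#' @param tau window size; must be one of `windowSizes(x)`.
#' @return the numeric value of the (variable, event, tau) cell.
#' @export
setGeneric("tfwfValue", function(x, variable, event, tau) standardGeneric("tfwfValue"))
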