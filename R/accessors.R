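#' @rdname accessors
#' @export
setMethod("fwfPlayer", "FWFMatrix", function(x) x@player)

#' @rdname accessors
#' @export
setMethod("fwfPlayer", "TFWFMatrix", function(x) x@player)

#' @rdname accessors
#' @export
setMethod("fwfPlayer", "InjuryVector", function(x) x@player)

#' @rdname accessors
#' @export
setMethod("fwfValues", "FWFMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fwfValues", "TFWFMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fwfVariables", "FWFMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("fwfVariables", "TFWFMatrix", function(x) dimnames(x@values)[[1L]])

#' @rdname accessors
#' @export
setMethod("eventIndices", "FWFMatrix", function(x) x@eventIndex)

#' @rdname accessors
#' @export
setMethod("eventIndices", "TFWFMatrix", function(x) x@eventIndex)

#' @rdname accessors
#' @export
setMethod("eventIndices", "InjuryVector", function(x) x@eventIndex)

#' @rdname accessors
#' @export
setMethod("windowSizes", "TFWFMatrix", function(x) x@taus)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureTable", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("sampleInfo", "FeatureTable", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("variantSpec", "FeatureTable", function(x) x@variant)

#' @rdname accessors
#' @export
setMethod("injuryLabels", "InjuryVector", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("seasonCalendar", "SeasonData", function(x) x@calendar)

#' @rdname accessors
#' @export
setMethod("seasonRecords", "SeasonData", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("seasonRoster", "SeasonData", function(x) x@roster)

#' @rdname accessors
#' @export
setMethod("seasonInjuries", "SeasonData", function(x) x@injuries)

#' @rdname tfwfValue
#' @export
setMethod("tfwfValue", "TFWFMatrix", function(x, variable, event, tau) {
  iv <- match(variable, fwfVariables(x))
  ie <- match(as.integer(event), x@eventIndex)
  it <- match(as.integer(tau), x@taus)
  if (is.na(iv)) stop("unknown variable: ", variable)
  if (is.na(ie)) stop("unknown event index: ", event)
  if (is.na(it)) stop("tau ", tau, " is not in the window set")
  x@values[iv, ie, it]
})

setMethod("show", "SeasonData", function(object) {
  cat("SeasonData:", length(object@roster), "players,",
      nrow(object@calendar), "events (",
      sum(object@calendar$event_type == "match"), "matches ),",
      nrow(object@records), "workload records,",
      nrow(object@injuries), "injuries\n")
})

setMethod("show", "FWFMatrix", function(object) {
  cat("FWFMatrix [", object@player, "]: ",
      nrow(object@values), " variables x ", ncol(object@values),
      " events (", object@missingPolicy, ")\n", sep = "")
})

setMethod("show", "TFWFMatrix", function(object) {
  d <- dim(object@values)
  cat("TFWFMatrix (", object@kind, ") [", object@player, "]: ",
      d[1], " variables x ", d[2], " events x ", d[3], " windows\n", sep = "")
})

setMethod("show", "InjuryVector", function(object) {
  cat("InjuryVector [", object@player, "]: ",
      sum(object@labels), " injuries over ", length(object@labels),
      " events\n", sep = "")
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable (", object@variant@variant, "): ",
      nrow(object@features), " samples x ", ncol(object@features),
      " features, ", sum(object@labels), " positives (prevalence ",
      signif(mean(object@labels), 3), ")\n", sep = "")
})

setMethod("show", "SeasonConfig", function(object) {
  cat("SeasonConfig:", object@nPlayers, "players,", object@nWeeks,
      "weeks,", object@nVariables, "variables; target prevalence",
      object@targetPrevalence, "\n")
})
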