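#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' SeasonData: one season of workload records, calendar, roster and injuries
#'
#' Container for the long-format season inputs. `records` holds one row per
#' (player, event, variable, value); `calendar` one row per event with its
#' date, type (training/match) and match-day offset (0 = match day, -1 = the
#' last training before it); `injuries` one row per reported injury. All
#' invariants (non-negative loads, unique keys, gap-free 0-based event index,
#' non-decreasing dates) are enforced by the validity method.
#'
#' @slot records data.frame with columns `player_id`, `event_index`,
#'   `variable`, `value`.
#' @slot calendar data.frame with columns `event_index`, `date`,
#'   `event_type`, `md_offset`.
#' @slot roster character vector of anonymized player identifiers.
#' @slot injuries data.frame with columns `player_id`, `event_index`,
#'   `injury_class`.
#' @export
setClass("SeasonData",
  representation(
    records  = "data.frame",
    calendar = "data.frame",
    roster   = "character",
    injuries = "data.frame"
  )
)

setValidity("SeasonData", function(object) {
  msg <- character()
  rec <- object@records
  cal <- object@calendar
  inj <- object@injuries
  need_rec <- c("player_id", "event_index", "variable", "value")
  need_cal <- c("event_index", "date", "event_type", "md_offset")
  need_inj <- c("player_id", "event_index", "injury_class")
  if (!all(need_rec %in% names(rec)))
    msg <- c(msg, paste("records must have columns:", paste(need_rec, collapse = ", ")))
  if (!all(need_cal %in% names(cal)))
    msg <- c(msg, paste("calendar must have columns:", paste(need_cal, collapse = ", ")))
  if (nrow(inj) > 0 && !all(need_inj %in% names(inj)))
    msg <- c(msg, paste("injuries must have columns:", paste(need_inj, collapse = ", ")))
  if (length(msg)) return(msg)

  ev <- cal$event_index
  if (nrow(cal) > 0) {
    if (!identical(as.integer(ev), seq.int(0L, length.out = nrow(cal))))
      msg <- c(msg, "calendar event_index must be 0-based, strictly increasing and gap-free")
    if (is.unsorted(cal$date))
      msg <- c(msg, "calendar dates must be non-decreasing")
    if (!all(cal$event_type %in% c("training", "match")))
      msg <- c(msg, "event_type must be 'training' or 'match'")
    if (any(cal$md_offset > 0))
      msg <- c(msg, "md_offset must be <= 0 (0 = match day)")
  }
  if (nrow(rec) > 0) {
    bad <- which(!is.finite(rec$value) | rec$value < 0)
    if (length(bad))
      msg <- c(msg, paste0("workload values must be finite and >= 0; first offending row: ", bad[1]))
    key <- paste(rec$player_id, rec$event_index, rec$variable, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (player, event, variable) records")
    if (!all(rec$event_index %in% ev))
      msg <- c(msg, "records reference event_index values absent from the calendar")
    if (!all(rec$player_id %in% object@roster))
      msg <- c(msg, "records reference players absent from the roster")
  }
  if (anyDuplicated(object@roster))
    msg <- c(msg, "roster identifiers must be unique")
  if (nrow(inj) > 0) {
    if (!all(inj$player_id %in% object@roster))
      msg <- c(msg, "injury report references players absent from the roster")
    if (!all(inj$event_index %in% ev))
      msg <- c(msg, "injury report references events absent from the calendar")
  }
  if (length(msg)) msg else TRUE
})

#' FWFMatrix: per-player variables-by-events workload matrix
#'
#' The workload footprint of one player: row i, column j holds the value of
#' variable i at event j. Under `zero_fill` every calendar event appears as a
#' column (absent records contribute 0); under `omit_event` only events the
#' player participated in appear.
#'
#' @slot player character(1) player identifier.
#' @slot values numeric matrix, variables in rows (rownames), events in
#'   columns.
#' @slot eventIndex integer vector of 0-based calendar event indices, one per
#'   column.
#' @slot missingPolicy `"zero_fill"` or `"omit_event"`.
#' @export
setClass("FWFMatrix",
  representation(
    player        = "character",
    values        = "matrix",
    eventIndex    = "integer",
    missingPolicy = "character"
  )
)

setValidity("FWFMatrix", function(object) {
  msg <- character()
  if (length(object@player) != 1L) msg <- c(msg, "player must be length 1")
  if (!object@missingPolicy %in% c("zero_fill", "omit_event"))
    msg <- c(msg, "missingPolicy must be 'zero_fill' or 'omit_event'")
  if (ncol(object@values) != length(object@eventIndex))
    msg <- c(msg, "eventIndex length must equal the number of columns")
  if (is.null(rownames(object@values)) && nrow(object@values) > 0)
    msg <- c(msg, "values must carry variable rownames")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "all workload values must be finite")
  if (length(msg)) msg else TRUE
})

#' TFWFMatrix: cumulative or temporal variation block of a workload footprint
#'
#' Stacks, for one player, the rolling-window features of every variable at
#' every event over a window set T: the cumulative block holds tau-acute
#' workloads (windowed sums), the temporal block their first differences
#' (delta acute-chronic workloads). Values are stored as a dense
#' variables x events x windows array addressable by [`tfwfValue()`].
#'
#' @slot player character(1) player identifier.
#' @slot values 3-d numeric array: variables x events x windows, with
#'   dimnames on all three axes.
#' @slot eventIndex integer vector of 0-based event indices (second axis).
#' @slot taus integer vector of window sizes (third axis), strictly
#'   increasing.
#' @slot kind `"cumulative"` or `"temporal"`.
#' @export
setClass("TFWFMatrix",
  representation(
    player     = "character",
    values     = "array",
    eventIndex = "integer",
    taus       = "integer",
    kind       = "character"
  )
)

setValidity("TFWFMatrix", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
  else {
    if (d[2] != length(object@eventIndex))
      msg <- c(msg, "second dimension must match eventIndex")
    if (d[3] != length(object@taus))
      msg <- c(msg, "third dimension must match taus")
  }
  if (is.unsorted(object@taus, strictly = TRUE) || any(object@taus < 1L))
    msg <- c(msg, "taus must be strictly increasing integers >= 1")
  if (!object@kind %in% c("cumulative", "temporal"))
    msg <- c(msg, "kind must be 'cumulative' or 'temporal'")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "all values must be finite")
  if (length(msg)) msg else TRUE
})

#' InjuryVector: binary per-event injury labels for one player
#'
#' @slot player character(1) player identifier.
#' @slot labels integer vector of 0/1 labels aligned to `eventIndex`.
#' @slot eventIndex integer vector of 0-based event indices.
#' @export
setClass("InjuryVector",
  representation(
    player     = "character",
    labels     = "integer",
    eventIndex = "integer"
  )
)

setValidity("InjuryVector", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@eventIndex))
    msg <- c(msg, "labels and eventIndex must have equal length")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' DatasetVariantSpec: configuration of one dataset design
#'
#' Five designs are supported: `baseline_raw` (raw per-event values,
#' participated events only), `acwr_uncoupled` / `acwr_coupled` / `acwr_ewma`
#' (per variable the acute, chronic and ratio triplet of the corresponding
#' ACWR method over a zero-filled calendar) and `fwf` (per variable and
#' window size the cumulative and differential pair).
#'
#' @slot variant one of `"baseline_raw"`, `"acwr_uncoupled"`,
#'   `"acwr_coupled"`, `"acwr_ewma"`, `"fwf"`.
#' @slot taus integer window set (required iff variant is `"fwf"`).
#' @slot missingPolicy missing-event policy passed to [buildFWF()].
#' @slot edgePolicy `"zero_pad"` or `"strict"` start-of-series policy.
#' @export
setClass("DatasetVariantSpec",
  representation(
    variant       = "character",
    taus          = "integerOrNULL",
    missingPolicy = "character",
    edgePolicy    = "character"
  )
)

setValidity("DatasetVariantSpec", function(object) {
  msg <- character()
  variants <- c("baseline_raw", "acwr_uncoupled", "acwr_coupled", "acwr_ewma", "fwf")
  if (!object@variant %in% variants)
    msg <- c(msg, paste("variant must be one of:", paste(variants, collapse = ", ")))
  if (object@variant == "fwf" && is.null(object@taus))
    msg <- c(msg, "variant 'fwf' requires a tau window set")
  if (!is.null(object@taus) &&
      (is.unsorted(object@taus, strictly = TRUE) || any(object@taus < 1L)))
    msg <- c(msg, "taus must be strictly increasing integers >= 1")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: labelled sample-by-feature table for one dataset variant
#'
#' Rows are (player, event) samples; columns are named features whose
#' provenance is encoded as `{variable}__{operator}__{tau}`. Labels are the
#' binary injury outcomes aligned to the rows.
#'
#' @slot features numeric matrix, samples in rows, features in columns.
#' @slot labels integer 0/1 vector, one per row.
#' @slot samples data.frame with columns `player_id` and `event_index`
#'   keying each row.
#' @slot variant the [DatasetVariantSpec-class] that produced the table.
#' @slot provenance list of assembly metadata (prevalence, tau set, policies).
#' @export
setClass("FeatureTable",
  representation(
    features   = "matrix",
    labels     = "integer",
    samples    = "data.frame",
    variant    = "DatasetVariantSpec",
    provenance = "list"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "one label per feature row required")
  if (nrow(object@features) != nrow(object@samples))
    msg <- c(msg, "one sample key per feature row required")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(object@features) && any(!is.finite(object@features)))
    msg <- c(msg, "feature values must be finite (no missing values after assembly)")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one classifier family plus hyperparameters and seed
#'
#' @slot family one of `"LDA"`, `"LR"`, `"NB"`, `"KNN"`, `"SVM"`, `"CART"`,
#'   `"RF"`, `"MLP"`.
#' @slot hyperparameters named list of family-specific settings.
#' @slot seed integer seed recorded for stochastic families.
#' @export
setClass("ModelSpec",
  representation(
    family          = "character",
    hyperparameters = "list",
    seed            = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  fams <- c("LDA", "LR", "NB", "KNN", "SVM", "CART", "RF", "MLP")
  if (!object@family %in% fams)
    return(paste("family must be one of:", paste(fams, collapse = ", ")))
  TRUE
})

#' SeasonConfig: parameters of the synthetic season generator
#'
#' Defines a multi-player season made of repeated microcycles (default
#' MD-4, MD-3, MD-2, MD-1, MD), per-variable lognormal workload baselines
#' with a match-day load shape, occasional load spikes, and a match-day
#' injury hazard driven by the recent change of one driver variable:
#' logistic(beta0 + beta1 * z) where z is the standardized difference
#' x(MD-1) - x(MD-1 - driverTau). beta0 is auto-calibrated by bisection so
#' the mean hazard matches `targetPrevalence`.
#'
#' @slot nPlayers integer number of players.
#' @slot nWeeks integer number of microcycles (one match each).
#' @slot microcycle integer vector of MD offsets making one week, ending in 0.
#' @slot nVariables integer number of workload variables.
#' @slot baselineMean positive numeric, per-variable lognormal location scale.
#' @slot baselineSd positive numeric, lognormal sigma (log scale).
#' @slot spikeProb probability that a (player, event) draws a load spike.
#' @slot spikeMult multiplicative spike magnitude (> 1).
#' @slot hazardBeta1 slope of the injury hazard on the standardized driver
#'   difference.
#' @slot driverVariable name of the hazard driver variable.
#' @slot driverTau event lag of the driving difference.
#' @slot participationRate probability a player takes part in an event.
#' @slot targetPrevalence mean match-day injury probability to calibrate to.
#' @slot trainingHazard hazard multiplier applied on training days (default 0:
#'   injuries concentrate in matches).
#' @export
setClass("SeasonConfig",
  representation(
    nPlayers          = "integer",
    nWeeks            = "integer",
    microcycle        = "integer",
    nVariables        = "integer",
    baselineMean      = "numeric",
    baselineSd        = "numeric",
    spikeProb         = "numeric",
    spikeMult         = "numeric",
    hazardBeta1       = "numeric",
    driverVariable    = "character",
    driverTau         = "integer",
    participationRate = "numeric",
    targetPrevalence  = "numeric",
    trainingHazard    = "numeric"
  )
)

setValidity("SeasonConfig", function(object) {
  msg <- character()
  if (object@nPlayers < 1L || object@nWeeks < 1L || object@nVariables < 1L)
    msg <- c(msg, "nPlayers, nWeeks and nVariables must be >= 1")
  if (utils::tail(object@microcycle, 1L) != 0L || any(object@microcycle > 0L))
    msg <- c(msg, "microcycle must be MD offsets <= 0 ending in 0 (match day)")
  if (any(object@baselineMean <= 0) || any(object@baselineSd <= 0))
    msg <- c(msg, "baselineMean and baselineSd must be positive")
  if (object@spikeProb < 0 || object@spikeProb > 1)
    msg <- c(msg, "spikeProb must be in [0, 1]")
  if (object@spikeMult <= 1)
    msg <- c(msg, "spikeMult must be > 1")
  if (object@participationRate <= 0 || object@participationRate > 1)
    msg <- c(msg, "participationRate must be in (0, 1]")
  if (object@targetPrevalence <= 0 || object@targetPrevalence >= 1)
    msg <- c(msg, "targetPrevalence must be in (0, 1)")
  if (object@driverTau < 1L)
    msg <- c(msg, "driverTau must be >= 1")
  if (length(msg)) msg else TRUE
})
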