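## Assembly of the five dataset variants and the pre-match undersampling.

#' Construct a dataset variant specification
#'
#' @param variant one of `"baseline_raw"`, `"acwr_uncoupled"`,
#'   `"acwr_coupled"`, `"acwr_ewma"`, `"fwf"`.
#' @param taus integer window set; required iff `variant = "fwf"`.
#' @param missingPolicy missing-event policy; `baseline_raw` keeps only
#'   participated events (`"omit_event"`), every other variant zero-fills the
#'   calendar so all players share one footprint shape.
#' @param edgePolicy start-of-series policy for the rolling operators.
#' @return a validated [DatasetVariantSpec-class].
#' @export
datasetVariantSpec <- function(variant, taus = NULL,
                               missingPolicy = if (variant == "baseline_raw")
                                 "omit_event" else "zero_fill",
                               edgePolicy = "zero_pad") {
  new("DatasetVariantSpec", variant = variant,
      taus = if (is.null(taus)) NULL else as.integer(taus),
      missingPolicy = missingPolicy, edgePolicy = edgePolicy)
}

.featureBlockForPlayer <- function(season, player, spec) {
  variant <- spec@variant
  if (variant == "baseline_raw") {
    fwf <- buildFWF(season, player, missingPolicy = "omit_event")
    feats <- t(fwfValues(fwf))
    colnames(feats) <- paste0(fwfVariables(fwf), "__raw__0")
    return(list(features = feats, events = eventIndices(fwf)))
  }
  fwf <- buildFWF(season, player, missingPolicy = "zero_fill")
  vals <- fwfValues(fwf)
  vars <- fwfVariables(fwf)
  nE <- ncol(vals)
  if (variant == "fwf") {
    cum <- cumulativeMatrix(fwf, spec@taus, spec@edgePolicy)
    tmp <- temporalMatrix(fwf, spec@taus, spec@edgePolicy)
    nT <- length(spec@taus)
    feats <- matrix(0, nrow = nE, ncol = 2L * length(vars) * nT)
    nm <- character(ncol(feats))
    k <- 0L
    for (v in seq_along(vars)) for (t in seq_len(nT)) {
      feats[, k + 1L] <- fwfValues(cum)[v, , t]
      feats[, k + 2L] <- fwfValues(tmp)[v, , t]
      nm[k + 1L] <- paste0(vars[v], "__aw__", spec@taus[t])
      nm[k + 2L] <- paste0(vars[v], "__acw__", spec@taus[t])
      k <- k + 2L
    }
    colnames(feats) <- nm
    return(list(features = feats, events = eventIndices(fwf)))
  }
  ## classical ACWR triplets, one per variable
  feats <- matrix(0, nrow = nE, ncol = 3L * length(vars))
  nm <- character(ncol(feats))
  for (v in seq_along(vars)) {
    s <- vals[v, ]
    k <- (v - 1L) * 3L
    if (variant == "acwr_ewma") {
      e7 <- ewmaSeries(s, 7L)
      e28 <- ewmaSeries(s, 28L)
      ratio <- ifelse(e28 == 0, NaN, e7 / e28)
      feats[, k + 1L] <- e7
      feats[, k + 2L] <- e28
      feats[, k + 3L] <- ifelse(is.nan(ratio), 0, ratio)
      nm[k + 1:3] <- paste0(vars[v], c("__ewma__7", "__ewma__28",
                                       "__acwr_ewma__28"))
    } else {
      aw <- .awMatrix(s, c(7L, 28L))
      aw7 <- aw[, 1L]
      if (variant == "acwr_coupled") {
        cw <- aw[, 2L] / 4
        nm[k + 1:3] <- paste0(vars[v], c("__aw__7", "__cw__28", "__acwr__28"))
      } else {
        cw <- (aw[, 2L] - aw7) / 3
        nm[k + 1:3] <- paste0(vars[v], c("__aw__7", "__cw__21", "__acwr__21"))
      }
      ratio <- ifelse(cw == 0, NaN, aw7 / cw)
      feats[, k + 1L] <- aw7
      feats[, k + 2L] <- cw
      feats[, k + 3L] <- ifelse(is.nan(ratio), 0, ratio)
    }
  }
  colnames(feats) <- nm
  list(features = feats, events = eventIndices(fwf))
}

#' Assemble a labelled feature table for one dataset variant
#'
#' Builds, per player, the footprint features of the requested variant and
#' stacks them into one (player, event) sample table with binary injury
#' labels from the injury report. Undefined ACWR ratios (zero chronic
#' denominator) are encoded as 0 so the table carries no missing values.
#' Rows are ordered by event index, then player, so temporal splitting can
#' rely on row order.
#'
#' @param season a [SeasonData-class].
#' @param spec a [DatasetVariantSpec-class].
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(season, spec) {
  stopifnot(is(spec, "DatasetVariantSpec"))
  validObject(spec)
  roster <- seasonRoster(season)
  blocks <- lapply(roster, function(p) {
    blk <- .featureBlockForPlayer(season, p, spec)
    iv <- buildInjuryVector(season, p)
    lab <- injuryLabels(iv)[match(blk$events, eventIndices(iv))]
    list(features = blk$features,
         samples = data.frame(player_id = p, event_index = blk$events,
                              stringsAsFactors = FALSE),
         labels = lab)
  })
  features <- do.call(rbind, lapply(blocks, `[[`, "features"))
  samples <- do.call(rbind, lapply(blocks, `[[`, "samples"))
  labels <- unlist(lapply(blocks, `[[`, "labels"))
  ord <- order(samples$event_index, samples$player_id)
  features <- features[ord, , drop = FALSE]
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  labels <- as.integer(labels[ord])
  new("FeatureTable", features = features, labels = labels,
      samples = samples, variant = spec,
      provenance = list(prevalence = mean(labels),
                        taus = spec@taus,
                        missingPolicy = spec@missingPolicy,
                        edgePolicy = spec@edgePolicy))
}

.subsetFeatureTable <- function(table, idx, labels = NULL) {
  samples <- table@samples[idx, , drop = FALSE]
  rownames(samples) <- NULL
  labels <- if (is.null(labels)) table@labels[idx] else as.integer(labels)
  new("FeatureTable",
      features = table@features[idx, , drop = FALSE],
      labels = labels, samples = samples, variant = table@variant,
      provenance = utils::modifyList(table@provenance,
                                     list(prevalence = mean(labels))))
}

#' Pre-match undersampling: keep only MD-1 rows of match participants
#'
#' Reduces the table to the rows at MD-1 events (the last training before a
#' match) for players who participated in the following match, and replaces
#' the labels with the MD-shifted labels of
#' [shiftMatchLabelsToMD1()], so an injury realized on match day is carried
#' by its MD-1 sample. Mid-week and match-day rows are removed; injuries at
#' events other than the retained MD-1 rows are dropped with a message.
#'
#' @param table a [FeatureTable-class] built from `season`.
#' @param season the [SeasonData-class] the table came from.
#' @return the undersampled [FeatureTable-class].
#' @export
undersamplePrematch <- function(table, season) {
  cal <- seasonCalendar(season)
  n <- nrow(cal)
  md1 <- which(cal$md_offset == -1L & c(cal$md_offset[-1L], NA) == 0L)
  if (length(md1) == 0L) {
    warning("calendar has no MD-1 events immediately preceding a match; ",
            "returning an empty table")
    return(.subsetFeatureTable(table, integer()))
  }
  part <- participationMatrix(season)
  roster <- seasonRoster(season)
  shifted <- lapply(roster, function(p)
    injuryLabels(shiftMatchLabelsToMD1(buildInjuryVector(season, p), cal)))
  names(shifted) <- roster

  samples <- sampleInfo(table)
  keep <- logical(nrow(samples))
  newlab <- integer(nrow(samples))
  md1Events <- cal$event_index[md1]
  matchEvents <- cal$event_index[md1 + 1L]
  for (i in seq_len(nrow(samples))) {
    e <- samples$event_index[i]
    k <- match(e, md1Events)
    if (is.na(k)) next
    p <- samples$player_id[i]
    if (!part[p, as.character(matchEvents[k])]) next
    keep[i] <- TRUE
    newlab[i] <- shifted[[p]][match(e, cal$event_index)]
  }
  lost <- sum(vapply(roster, function(p) sum(shifted[[p]]), 1L)) -
    sum(newlab[keep])
  if (lost > 0)
    message(lost, " injury label(s) fell outside the retained MD-1 rows ",
            "and were dropped")
  .subsetFeatureTable(table, which(keep), labels = newlab[keep])
}
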