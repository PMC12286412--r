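## Season data model: loading the long-format tables, building per-player
## footprints and injury vectors, and relocating match-day labels to MD-1.

#' Construct a SeasonData object from its component tables
#'
#' Validates all invariants (see [SeasonData-class]). `calendar` is sorted by
#' event index; `roster` defaults to the players seen in the records.
#'
#' @param records data.frame with columns `player_id`, `event_index`,
#'   `variable`, `value`.
#' @param calendar data.frame with columns `event_index`, `date`,
#'   `event_type`, `md_offset`.
#' @param roster character vector of player identifiers.
#' @param injuries data.frame with columns `player_id`, `event_index`,
#'   `injury_class` (may be empty).
#' @return a validated [SeasonData-class].
#' @export
seasonData <- function(records, calendar,
                       roster = sort(unique(records$player_id)),
                       injuries = data.frame(player_id = character(),
                                             event_index = integer(),
                                             injury_class = character())) {
  calendar <- calendar[order(calendar$event_index), , drop = FALSE]
  rownames(calendar) <- NULL
  records$event_index <- as.integer(records$event_index)
  calendar$event_index <- as.integer(calendar$event_index)
  calendar$md_offset <- as.integer(calendar$md_offset)
  if (nrow(injuries)) injuries$event_index <- as.integer(injuries$event_index)
  new("SeasonData", records = records, calendar = calendar,
      roster = as.character(roster), injuries = injuries)
}

#' Load a season from long-format CSV files
#'
#' Reads the workload table (one row per player, event, variable, value plus
#' the calendar columns) and an optional injury report, reconstructs the
#' calendar, and validates every invariant. Column names can be remapped via
#' `schema`.
#'
#' @param path path to the workload CSV with (at least) columns `player_id`,
#'   `event_index`, `date`, `event_type`, `md_offset`, `variable`, `value`.
#' @param injuryPath optional path to the injury CSV with columns
#'   `player_id`, `event_index`, `injury_class`.
#' @param schema named character vector mapping the canonical column names to
#'   the names used in the file, e.g. `c(player_id = "athlete")`.
#' @return a [SeasonData-class].
#' @export
loadWorkloadTable <- function(path, injuryPath = NULL, schema = character()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("player_id", "event_index", "date", "event_type",
             "md_offset", "variable", "value")
  cols <- stats::setNames(canon, canon)
  cols[names(schema)] <- schema
  missing <- cols[!cols %in% names(raw)]
  if (length(missing))
    stop("schema error: missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df <- stats::setNames(raw[, cols, drop = FALSE], canon)
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad))
    stop("validation error: negative or non-finite workload value at row ",
         bad[1], " of ", path)
  calendar <- unique(df[, c("event_index", "date", "event_type", "md_offset")])
  if (anyDuplicated(calendar$event_index))
    stop("validation error: conflicting calendar rows for one event_index")
  records <- df[, c("player_id", "event_index", "variable", "value")]
  injuries <- if (is.null(injuryPath)) {
    data.frame(player_id = character(), event_index = integer(),
               injury_class = character())
  } else {
    inj <- utils::read.csv(injuryPath, stringsAsFactors = FALSE)
    need <- c("player_id", "event_index", "injury_class")
    if (!all(need %in% names(inj)))
      stop("schema error: injury report must have columns ",
           paste(need, collapse = ", "))
    inj[, need]
  }
  seasonData(records, calendar, injuries = injuries)
}

#' Write a season back to long-format CSV files
#'
#' Inverse of [loadWorkloadTable()]: joins the records with the calendar
#' columns and writes the workload table, and optionally the injury report.
#'
#' @param season a [SeasonData-class].
#' @param path output path for the workload CSV.
#' @param injuryPath optional output path for the injury CSV.
#' @return `path`, invisibly.
#' @export
writeSeasonCSV <- function(season, path, injuryPath = NULL) {
  cal <- seasonCalendar(season)
  rec <- seasonRecords(season)
  m <- match(rec$event_index, cal$event_index)
  out <- data.frame(player_id = rec$player_id,
                    event_index = rec$event_index,
                    date = cal$date[m],
                    event_type = cal$event_type[m],
                    md_offset = cal$md_offset[m],
                    variable = rec$variable,
                    value = rec$value)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(injuryPath))
    utils::write.csv(seasonInjuries(season), injuryPath, row.names = FALSE)
  invisible(path)
}

#' Build the workload footprint matrix of one player
#'
#' Arranges a player's per-event values into a variables-by-events matrix.
#' Under `zero_fill` every calendar event appears as a column and events
#' without a record (non-participation) contribute 0; under `omit_event`
#' those columns are dropped entirely, so the footprint width varies by
#' player.
#'
#' @param season a [SeasonData-class].
#' @param player player identifier, must be in the roster.
#' @param variables variable names to include (default: all seen in the
#'   records, sorted).
#' @param missingPolicy `"zero_fill"` or `"omit_event"`.
#' @return an [FWFMatrix-class].
#' @export
buildFWF <- function(season, player, variables = NULL,
                     missingPolicy = c("zero_fill", "omit_event")) {
  missingPolicy <- match.arg(missingPolicy)
  rec <- seasonRecords(season)
  if (!player %in% seasonRoster(season))
    stop("unknown player: ", player)
  if (is.null(variables)) variables <- sort(unique(rec$variable))
  if (length(variables) == 0L) stop("variables must be non-empty")
  if (!all(variables %in% rec$variable))
    stop("unknown variable(s): ",
         paste(setdiff(variables, rec$variable), collapse = ", "))
  cal <- seasonCalendar(season)
  mine <- rec[rec$player_id == player & rec$variable %in% variables, ,
              drop = FALSE]
  events <- cal$event_index
  if (missingPolicy == "omit_event")
    events <- intersect(events, sort(unique(mine$event_index)))
  vals <- matrix(0, nrow = length(variables), ncol = length(events),
                 dimnames = list(variables, as.character(events)))
  if (nrow(mine)) {
    iv <- match(mine$variable, variables)
    ie <- match(mine$event_index, events)
    keep <- !is.na(ie)
    vals[cbind(iv[keep], ie[keep])] <- mine$value[keep]
  }
  new("FWFMatrix", player = player, values = vals,
      eventIndex = as.integer(events), missingPolicy = missingPolicy)
}

#' Build the binary injury vector of one player
#'
#' labels\[j\] = 1 iff the injury report contains an entry for (player,
#' event j); aligned to the full calendar.
#'
#' @param season a [SeasonData-class].
#' @param player player identifier.
#' @return an [InjuryVector-class] aligned to the calendar.
#' @export
buildInjuryVector <- function(season, player) {
  cal <- seasonCalendar(season)
  inj <- seasonInjuries(season)
  hit <- inj$event_index[inj$player_id == player]
  labels <- as.integer(cal$event_index %in% hit)
  new("InjuryVector", player = player, labels = labels,
      eventIndex = as.integer(cal$event_index))
}

#' Relocate match-day injury labels to the preceding MD-1 event
#'
#' The pre-match question is asked at MD-1, so an injury realized on match
#' day (MD, offset 0) is associated with the immediately preceding event
#' tagged MD-1. Matches with an injury but no MD-1 predecessor drop the
#' label with a warning. Labels already off match day are untouched.
#'
#' @param iv an [InjuryVector-class] aligned to the calendar.
#' @param calendar the season calendar (with `md_offset` tags).
#' @return a new [InjuryVector-class] with relocated labels.
#' @export
shiftMatchLabelsToMD1 <- function(iv, calendar) {
  calendar <- calendar[order(calendar$event_index), , drop = FALSE]
  if (!identical(as.integer(calendar$event_index), iv@eventIndex))
    stop("injury vector and calendar cover different events")
  labels <- iv@labels
  md <- which(calendar$md_offset == 0L & labels == 1L)
  for (i in md) {
    if (i > 1L && calendar$md_offset[i - 1L] == -1L) {
      labels[i - 1L] <- 1L
      labels[i] <- 0L
    } else {
      warning("injury at match event ", calendar$event_index[i],
              " has no MD-1 predecessor; label dropped")
      labels[i] <- 0L
    }
  }
  new("InjuryVector", player = iv@player, labels = labels,
      eventIndex = iv@eventIndex)
}

#' Participation indicator per (player, event)
#'
#' A player participates in an event iff at least one workload record exists
#' for that pair.
#'
#' @param season a [SeasonData-class].
#' @return logical matrix, players (roster order) x events.
#' @export
participationMatrix <- function(season) {
  cal <- seasonCalendar(season)
  rec <- seasonRecords(season)
  roster <- seasonRoster(season)
  out <- matrix(FALSE, nrow = length(roster), ncol = nrow(cal),
                dimnames = list(roster, as.character(cal$event_index)))
  if (nrow(rec)) {
    ip <- match(rec$player_id, roster)
    ie <- match(rec$event_index, cal$event_index)
    out[unique(cbind(ip, ie))] <- TRUE
  }
  out
}

#' Export a footprint as a wide CSV
#'
#' Rows are variables, columns are event indices.
#'
#' @param fwf an [FWFMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFWFMatrix <- function(fwf, path) {
  df <- data.frame(variable = fwfVariables(fwf), fwfValues(fwf),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
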