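## Rolling cumulative and differential workload operators.
##
## All operators act on a per-event numeric series (one workload variable of
## one player, events in chronological order) and index events by their
## 1-based position in that series. Windows count events, not calendar days:
## tau = 7 means the last seven recorded events.

.checkEdge <- function(edge) match.arg(edge, c("zero_pad", "strict"))

.checkIndex <- function(series, j) {
  if (!is.numeric(series) || length(series) == 0L)
    stop("series must be a non-empty numeric vector")
  if (j < 1L || j > length(series))
    stop("event position j = ", j, " outside series of length ", length(series))
}

#' Tau-acute workload: rolling sum over the last tau events
#'
#' Sums a workload series over the window of `tau` consecutive events ending
#' at position `j`: x(j) + x(j-1) + ... + x(j-tau+1). With `tau = 7` this is
#' the classical weekly acute workload ("fatigue").
#'
#' @param series numeric per-event workload values, chronological order.
#' @param j 1-based event position at which the window ends.
#' @param tau integer window size, >= 1.
#' @param edge start-of-series policy: `"zero_pad"` treats events before the
#'   series start as zero load; `"strict"` raises an insufficient-history
#'   error when the window reaches before the first event.
#' @return the windowed sum (numeric scalar).
#' @seealso [chronicWorkload28()], [deltaACW()], [cumulativeMatrix()]
#' @examples
#' acuteWorkload(c(1.5, 0.33, 1.5, 0.33, 1.5, 0.33, 1.5), j = 7, tau = 7)
#' @export
acuteWorkload <- function(series, j, tau, edge = c("zero_pad", "strict")) {
  edge <- .checkEdge(edge)
  .checkIndex(series, j)
  if (tau < 1L) stop("tau must be >= 1")
  lo <- j - (tau - 1L)
  if (lo < 1L) {
    if (edge == "strict")
      stop("insufficient history: window of size ", tau,
           " ending at j = ", j, " reaches before the first event")
    lo <- 1L
  }
  sum(series[lo:j])
}

#' Coupled chronic workload: four-week rolling average
#'
#' Mean of the four consecutive, non-overlapping weekly (7-event) acute
#' workloads ending at position `j`; algebraically the sum of the last 28
#' events divided by 4. The current acute week is included (the "coupled"
#' formulation).
#'
#' @inheritParams acuteWorkload
#' @return the chronic workload CW28 (numeric scalar).
#' @export
chronicWorkload28 <- function(series, j, edge = c("zero_pad", "strict")) {
  acuteWorkload(series, j, 28L, edge) / 4
}

#' Uncoupled chronic workload: three prior weekly blocks
#'
#' Mean of the three weekly (7-event) acute workloads preceding the current
#' acute week: the sum of events j-27 ... j-7 divided by 3. Excluding the
#' acute week removes the mathematical coupling between numerator and
#' denominator of the classical ratio.
#'
#' @inheritParams acuteWorkload
#' @return the chronic workload CW21 (numeric scalar).
#' @export
chronicWorkload21 <- function(series, j, edge = c("zero_pad", "strict")) {
  (acuteWorkload(series, j, 28L, edge) - acuteWorkload(series, j, 7L, edge)) / 3
}

#' Coupled acute:chronic workload ratio
#'
#' AW7 / CW28 at position `j`. A zero chronic denominator (a legitimate
#' pre-season state) yields `NaN` as the tagged undefined value, never an
#' error or a silent zero.
#'
#' @inheritParams acuteWorkload
#' @return the ratio, or `NaN` when the chronic load is zero.
#' @export
acwrCoupled <- function(series, j, edge = c("zero_pad", "strict")) {
  aw <- acuteWorkload(series, j, 7L, edge)
  cw <- chronicWorkload28(series, j, edge)
  if (cw == 0) NaN else aw / cw
}

#' Uncoupled acute:chronic workload ratio
#'
#' AW7 / CW21 at position `j`; `NaN` when the chronic load is zero.
#'
#' @inheritParams acuteWorkload
#' @return the ratio, or `NaN` when the chronic load is zero.
#' @export
acwrUncoupled <- function(series, j, edge = c("zero_pad", "strict")) {
  aw <- acuteWorkload(series, j, 7L, edge)
  cw <- chronicWorkload21(series, j, edge)
  if (cw == 0) NaN else aw / cw
}

#' Exponentially weighted moving average of a workload series
#'
#' Murray-style EWMA with span `N`: EWMA\[j\] = lambda * x\[j\] +
#' (1 - lambda) * EWMA\[j-1\], lambda = 2 / (N + 1). Initialisation either at
#' the first observed value (`"first_value"`, the fixed point of a constant
#' series) or at zero.
#'
#' @param series numeric per-event workload values.
#' @param N integer span in events, >= 1.
#' @param init `"first_value"` or `"zero"`.
#' @return numeric vector of the same length as `series`.
#' @export
ewmaSeries <- function(series, N, init = c("first_value", "zero")) {
  init <- match.arg(init)
  if (length(series) == 0L) stop("series must be non-empty")
  if (N < 1L) stop("span N must be >= 1")
  lambda <- 2 / (N + 1)
  out <- numeric(length(series))
  out[1L] <- if (init == "first_value") series[1L] else lambda * series[1L]
  if (length(series) > 1L)
    for (j in 2:length(series))
      out[j] <- lambda * series[j] + (1 - lambda) * out[j - 1L]
  out
}

#' EWMA acute:chronic workload ratio
#'
#' Ratio of the span-7 to the span-28 EWMA of the series at position `j`;
#' `NaN` when the denominator is zero.
#'
#' @inheritParams acuteWorkload
#' @param init EWMA initialisation policy, see [ewmaSeries()].
#' @return the ratio, or `NaN` when the denominator is zero.
#' @export
acwrEWMA <- function(series, j, init = c("first_value", "zero")) {
  init <- match.arg(init)
  .checkIndex(series, j)
  num <- ewmaSeries(series, 7L, init)[j]
  den <- ewmaSeries(series, 28L, init)[j]
  if (den == 0) NaN else num / den
}

#' Delta acute-chronic workload: first difference of tau-acute workloads
#'
#' AW(j, tau) - AW(j-1, tau), which telescopes exactly to
#' x(j) - x(j - tau): the change in load relative to the event that dropped
#' out of the window. This is the cell type of the temporal variation block.
#' The telescoped form is evaluated directly, so the result is exact rather
#' than a difference of two rounded sums.
#'
#' @inheritParams acuteWorkload
#' @return the differenced workload (numeric scalar; may be negative).
#' @export
deltaACW <- function(series, j, tau, edge = c("zero_pad", "strict")) {
  edge <- .checkEdge(edge)
  .checkIndex(series, j)
  if (tau < 1L) stop("tau must be >= 1")
  if (edge == "strict" && j - tau < 1L)
    stop("insufficient history for deltaACW at j = ", j, ", tau = ", tau)
  lag <- if (j - tau >= 1L) series[j - tau] else 0
  series[j] - lag
}

## Vectorized all-(j, tau) acute workloads via a cumulative sum; zero_pad only.
.awMatrix <- function(series, taus) {
  cs <- cumsum(c(0, series))
  nE <- length(series)
  out <- matrix(0, nrow = nE, ncol = length(taus))
  for (t in seq_along(taus)) {
    j <- seq_len(nE)
    lo <- pmax(j - taus[t], 0L)
    out[, t] <- cs[j + 1L] - cs[lo + 1L]
  }
  out
}

.makeTFWF <- function(fwf, taus, kind, values) {
  dimnames(values) <- list(fwfVariables(fwf),
                           as.character(fwf@eventIndex),
                           as.character(taus))
  new("TFWFMatrix", player = fwf@player, values = values,
      eventIndex = fwf@eventIndex, taus = as.integer(taus), kind = kind)
}

#' Cumulative variation block of a workload footprint
#'
#' For every variable, event and window size in `taus`, the tau-acute
#' workload (rolling sum). The printed block shape is
#' variables x (events * windows); values are stored as a 3-d array with
#' explicit (variable, event, tau) axis labels so the flattening order is
#' unambiguous.
#'
#' @param fwf a zero-filled [FWFMatrix-class].
#' @param taus integer vector of window sizes, strictly increasing.
#' @param edge start-of-series policy; `"strict"` requires
#'   `max(taus) <= ncol(fwf)` and full history at every cell, so the default
#'   `"zero_pad"` (season start = zero load) is used for whole-season blocks.
#' @return a [TFWFMatrix-class] of kind `"cumulative"`.
#' @export
cumulativeMatrix <- function(fwf, taus, edge = c("zero_pad", "strict")) {
  edge <- .checkEdge(edge)
  stopifnot(is(fwf, "FWFMatrix"))
  if (fwf@missingPolicy != "zero_fill")
    stop("cumulative/temporal blocks require a zero_fill footprint")
  taus <- as.integer(taus)
  if (length(taus) == 0L || is.unsorted(taus, strictly = TRUE) || any(taus < 1L))
    stop("taus must be a non-empty strictly increasing set of integers >= 1")
  nE <- ncol(fwf@values)
  if (edge == "strict" && max(taus) > nE)
    stop("strict edge policy: max(taus) exceeds the number of events")
  vals <- array(0, dim = c(nrow(fwf@values), nE, length(taus)))
  for (v in seq_len(nrow(fwf@values)))
    vals[v, , ] <- .awMatrix(fwf@values[v, ], taus)
  .makeTFWF(fwf, taus, "cumulative", vals)
}

#' Temporal variation block of a workload footprint
#'
#' For every variable, event and window size, the delta acute-chronic
#' workload: the first difference in events of the cumulative block, equal to
#' x(j) - x(j - tau) cell by cell.
#'
#' @inheritParams cumulativeMatrix
#' @return a [TFWFMatrix-class] of kind `"temporal"`.
#' @export
temporalMatrix <- function(fwf, taus, edge = c("zero_pad", "strict")) {
  ## validate exactly as the cumulative block does
  cum <- cumulativeMatrix(fwf, taus, edge)
  x <- fwf@values
  nE <- ncol(x)
  out <- cum@values
  for (t in seq_along(cum@taus)) {
    tau <- cum@taus[t]
    lagged <- cbind(matrix(0, nrow(x), min(tau, nE)),
                    x[, seq_len(max(nE - tau, 0L)), drop = FALSE])
    out[, , t] <- x - lagged   # telescoped form: x(j) - x(j - tau)
  }
  cum@values <- out
  cum@kind <- "temporal"
  validObject(cum)
  cum
}
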