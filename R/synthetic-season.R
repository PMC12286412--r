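## Synthetic multi-player season generator: microcycle calendar, lognormal
## workload records with occasional spikes, and a match-day injury hazard
## driven by the recent change of one driver variable, so the differential
## workload features carry recoverable signal.

#' Construct a synthetic season configuration
#'
#' See [SeasonConfig-class] for the meaning of every field. Defaults describe
#' a mid-sized squad with weekly microcycles MD-4 ... MD-1, MD, lognormal
#' per-variable loads shaped by the training week (heavier MD-3 and match
#' day, lighter MD-1), and an injury hazard acting on match days only.
#'
#' @param nPlayers,nWeeks,nVariables season dimensions.
#' @param microcycle integer MD offsets making up one week, ending in 0.
#' @param baselineMean per-variable lognormal location (recycled).
#' @param baselineSd lognormal sigma on the log scale.
#' @param spikeProb probability of a load spike per (player, event).
#' @param spikeMult spike magnitude multiplier (> 1).
#' @param hazardBeta1 hazard slope on the standardized driver difference.
#' @param driverVariable hazard driver variable name.
#' @param driverTau event lag of the driving difference.
#' @param participationRate per-(player, event) participation probability.
#' @param targetPrevalence mean match-day injury probability after
#'   calibration.
#' @param trainingHazard multiplier on the hazard for training events
#'   (default 0: injuries concentrate in matches).
#' @return a validated [SeasonConfig-class].
#' @export
seasonConfig <- function(nPlayers = 23L, nWeeks = 45L,
                         microcycle = c(-4L, -3L, -2L, -1L, 0L),
                         nVariables = 10L,
                         baselineMean = 1 + ((seq_len(nVariables) - 1L) %% 7L) * 0.5,
                         baselineSd = 0.5,
                         spikeProb = 0.08, spikeMult = 2.5,
                         hazardBeta1 = 1.5,
                         driverVariable = "v01", driverTau = 3L,
                         participationRate = 0.85,
                         targetPrevalence = 0.03,
                         trainingHazard = 0) {
  baselineMean <- rep_len(baselineMean, nVariables)
  cfg <- new("SeasonConfig",
             nPlayers = as.integer(nPlayers), nWeeks = as.integer(nWeeks),
             microcycle = as.integer(microcycle),
             nVariables = as.integer(nVariables),
             baselineMean = baselineMean, baselineSd = baselineSd,
             spikeProb = spikeProb, spikeMult = spikeMult,
             hazardBeta1 = hazardBeta1, driverVariable = driverVariable,
             driverTau = as.integer(driverTau),
             participationRate = participationRate,
             targetPrevalence = targetPrevalence,
             trainingHazard = trainingHazard)
  if (!driverVariable %in% .variableNames(cfg))
    stop("driverVariable '", driverVariable,
         "' does not exist among the generated variables")
  cfg
}

.variableNames <- function(config) sprintf("v%02d", seq_len(config@nVariables))

## Within-week load shape by MD offset: match day and MD-3 are the heavy
## sessions, MD-1 is the light pre-match activation.
.mdShape <- function(mdOffset) {
  shape <- c("0" = 1.3, "-1" = 0.6, "-2" = 0.9, "-3" = 1.2, "-4" = 1.0)
  out <- shape[as.character(mdOffset)]
  out[is.na(out)] <- 1.0
  unname(out)
}

#' Preset season configurations
#'
#' `"paper_scale"` emulates a full elite-club season: 23 players, 45 weekly
#' microcycles (225 events), 73 workload variables, participation tuned so
#' roughly 4,100 player-event samples are realized, and a match-day injury
#' prevalence calibrated to produce on the order of 20-25 injuries.
#' `"smoke_test"` is a minimal 6-player, 8-week, 5-variable season with an
#' elevated prevalence so stratified resampling remains feasible at tiny
#' scale.
#'
#' @param preset `"paper_scale"` or `"smoke_test"`.
#' @return a [SeasonConfig-class].
#' @export
emulatePaperScale <- function(preset = c("paper_scale", "smoke_test")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale")
    seasonConfig(nPlayers = 23L, nWeeks = 45L, nVariables = 73L,
                 participationRate = 0.8, targetPrevalence = 0.028,
                 spikeProb = 0.08, spikeMult = 2.5,
                 hazardBeta1 = 1.5, driverTau = 3L)
  else
    seasonConfig(nPlayers = 6L, nWeeks = 8L, nVariables = 5L,
                 participationRate = 0.9, targetPrevalence = 0.15,
                 spikeProb = 0.15, spikeMult = 3,
                 hazardBeta1 = 5, driverTau = 3L)
}

## Calibrate the hazard intercept by bisection so the mean simulated
## probability over eligible (player, match) pairs hits the target.
.calibrateBeta0 <- function(z, beta1, target) {
  f <- function(b0) mean(stats::plogis(b0 + beta1 * z)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible hazard calibration: target prevalence ", target,
         " unreachable (achievable range [",
         signif(mean(stats::plogis(lo + beta1 * z)), 3), ", ",
         signif(mean(stats::plogis(hi + beta1 * z)), 3), "])")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic season
#'
#' Draws the calendar, participation, workload records, spikes and injuries
#' of one season under `config`, fully determined by `seed`. Workloads are
#' lognormal around a per-variable baseline shaped by the microcycle, with
#' spikes of probability `spikeProb` and magnitude `spikeMult` applied to
#' all variables of the affected (player, event). The match-day injury
#' probability is `plogis(beta0 + beta1 * z)` where `z` is the standardized
#' driver-variable difference x(MD-1) - x(MD-1 - driverTau) on the
#' zero-filled series, and `beta0` is calibrated by bisection so the mean
#' probability equals `targetPrevalence`. Only players participating in the
#' match are at risk; training events carry `trainingHazard` times the
#' hazard (0 by default).
#'
#' @param config a [SeasonConfig-class].
#' @param seed integer seed controlling every draw.
#' @return list with `season` (a [SeasonData-class]) and `truth` (list:
#'   per-(player, match) data.frame `hazard` with driver difference,
#'   probability and realized label; `spikes` log; calibrated `beta0`).
#' @export
generateSeason <- function(config, seed = 1L) {
  validObject(config)
  set.seed(seed)
  mc <- config@microcycle
  nE <- config@nWeeks * length(mc)
  offsets <- rep(mc, config@nWeeks)
  calendar <- data.frame(
    event_index = seq_len(nE) - 1L,
    date = as.character(as.Date("2023-07-10") +
                          rep((seq_len(config@nWeeks) - 1L) * 7L,
                              each = length(mc)) +
                          seq_len(length(mc)) - 1L),
    event_type = ifelse(offsets == 0L, "match", "training"),
    md_offset = offsets,
    stringsAsFactors = FALSE
  )
  players <- sprintf("p%02d", seq_len(config@nPlayers))
  vars <- .variableNames(config)
  shape <- .mdShape(offsets)

  part <- matrix(stats::runif(config@nPlayers * nE) <= config@participationRate,
                 nrow = config@nPlayers, dimnames = list(players, NULL))
  spike <- matrix(stats::runif(config@nPlayers * nE) < config@spikeProb,
                  nrow = config@nPlayers, dimnames = list(players, NULL))

  nV <- config@nVariables
  meanlog <- log(outer(config@baselineMean, shape))  # V x E
  records <- vector("list", config@nPlayers)
  driver <- matrix(0, nrow = config@nPlayers, ncol = nE,
                   dimnames = list(players, NULL))
  dIdx <- match(config@driverVariable, vars)
  for (p in seq_len(config@nPlayers)) {
    vals <- matrix(stats::rlnorm(nV * nE, meanlog = meanlog,
                                 sdlog = config@baselineSd), nrow = nV)
    vals[, spike[p, ]] <- vals[, spike[p, ]] * config@spikeMult
    zeroed <- vals
    zeroed[, !part[p, ]] <- 0
    driver[p, ] <- zeroed[dIdx, ]
    keep <- which(part[p, ])
    records[[p]] <- data.frame(
      player_id = players[p],
      event_index = rep(keep - 1L, each = nV),
      variable = rep(vars, times = length(keep)),
      value = as.numeric(zeroed[, keep]),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, records)

  ## hazard over eligible (player, match) pairs: participation in the match
  matchPos <- which(offsets == 0L)
  elig <- NULL
  for (m in matchPos) {
    md1 <- m - 1L
    who <- which(part[, m])
    if (length(who) == 0L || md1 < 1L) next
    lagPos <- md1 - config@driverTau
    lagVal <- if (lagPos >= 1L) driver[who, lagPos] else 0
    elig <- rbind(elig, data.frame(
      player_id = players[who],
      event_index = m - 1L,
      driver_diff = driver[who, md1] - lagVal,
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(elig) || nrow(elig) == 0L)
    stop("no eligible (player, match) pairs; season too small")
  sdd <- stats::sd(elig$driver_diff)
  z <- if (is.finite(sdd) && sdd > 0)
    (elig$driver_diff - mean(elig$driver_diff)) / sdd
  else rep(0, nrow(elig))
  beta0 <- .calibrateBeta0(z, config@hazardBeta1, config@targetPrevalence)
  prob <- stats::plogis(beta0 + config@hazardBeta1 * z)
  label <- as.integer(stats::runif(nrow(elig)) < prob)

  injuries <- data.frame(player_id = elig$player_id[label == 1L],
                         event_index = elig$event_index[label == 1L],
                         injury_class = "muscle_grade_I_II",
                         stringsAsFactors = FALSE)
  season <- seasonData(records, calendar, roster = players,
                       injuries = injuries)
  spikeLog <- data.frame(player_id = rep(players, times = nE),
                         event_index = rep(seq_len(nE) - 1L,
                                           each = config@nPlayers))
  spikeLog <- spikeLog[as.vector(spike), , drop = FALSE]
  rownames(spikeLog) <- NULL
  truth <- list(hazard = cbind(elig, z = z, prob = prob, label = label),
                spikes = spikeLog, beta0 = beta0)
  list(season = season, truth = truth)
}
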