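# Fixtures built in code: the printed worked-example load series and small
# deterministic seasons.

# Alternating-load training week whose printed weekly total is 7 units.
table3Loads <- function() c(1.5, 0.33, 1.5, 0.33, 1.5, 0.33, 1.5)

# 28-event (four-week) series for the three illustrative players: weeks 1-3
# are the alternating pattern for everyone; week 4 differs per player but
# always sums to 7 units.
table4Series <- function(player = c("f1", "f2", "f3")) {
  player <- match.arg(player)
  w <- table3Loads()
  w4 <- switch(player,
    f1 = c(0, 0, 0, 0, 0, 0, 7),
    f2 = rep(1, 7),
    f3 = w
  )
  c(rep(w, 3), w4)
}

# Deterministic toy season: nPlayers players over nWeeks microcycles of
# (-2, -1, 0); every player has one record per event for each variable
# unless (player, event) is listed in `benched`.
toySeason <- function(nPlayers = 2L, nWeeks = 4L,
                      variables = c("dist", "sprint"),
                      benched = NULL, injuries = NULL) {
  mc <- c(-2L, -1L, 0L)
  nE <- nWeeks * length(mc)
  calendar <- data.frame(
    event_index = seq_len(nE) - 1L,
    date = as.character(as.Date("2024-01-01") + seq_len(nE) - 1L),
    event_type = ifelse(rep(mc, nWeeks) == 0L, "match", "training"),
    md_offset = rep(mc, nWeeks)
  )
  players <- paste0("p", seq_len(nPlayers))
  grid <- expand.grid(player_id = players, event_index = seq_len(nE) - 1L,
                      variable = variables, stringsAsFactors = FALSE)
  # deterministic positive values: a simple arithmetic pattern
  grid$value <- 1 + (match(grid$player_id, players) +
                       grid$event_index +
                       match(grid$variable, variables)) %% 5
  if (!is.null(benched)) {
    drop <- paste(grid$player_id, grid$event_index) %in%
      paste(benched$player_id, benched$event_index)
    grid <- grid[!drop, , drop = FALSE]
  }
  inj <- if (is.null(injuries))
    data.frame(player_id = character(), event_index = integer(),
               injury_class = character())
  else injuries
  seasonData(grid, calendar, roster = players, injuries = inj)
}

# Stratified-CV AUC pipeline used by permutation tests in the suite.
ldaPcaAucPipeline <- function(x, y) {
  if (sum(y) < 2L) return(0.5)
  ft <- featureTable(x, y)
  red <- pcaReduce(ft, ft, 0.95)$train
  cv <- crossValidate(red, modelSpec("LDA"), repeats = 1L, folds = 2L,
                      seed = 5L)
  mean(cv$validation$roc_auc, na.rm = TRUE)
}
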