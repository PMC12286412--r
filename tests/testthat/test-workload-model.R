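test_that("loading a toy CSV reproduces the records and the calendar", {
  csv <- file.path(tempdir(), "toy.csv")
  writeLines(c(
    "player_id,event_index,date,event_type,md_offset,variable,value",
    "p1,0,2024-01-01,training,-2,dist,10",
    "p1,0,2024-01-01,training,-2,sprint,2",
    "p1,1,2024-01-02,training,-1,dist,5",
    "p1,1,2024-01-02,training,-1,sprint,1",
    "p1,2,2024-01-03,match,0,dist,12",
    "p1,2,2024-01-03,match,0,sprint,4"
  ), csv)
  season <- loadWorkloadTable(csv)
  expect_s4_class(season, "SeasonData")
  expect_equal(nrow(seasonRecords(season)), 6L)
  expect_equal(nrow(seasonCalendar(season)), 3L)
  expect_equal(seasonRoster(season), "p1")
  expect_equal(seasonCalendar(season)$event_type, c("training", "training", "match"))
})

test_that("schema and invariant violations are rejected with clear errors", {
  csv <- file.path(tempdir(), "bad.csv")
  writeLines(c(
    "player_id,event_index,date,event_type,md_offset,variable,value",
    "p1,0,2024-01-01,training,-1,dist,-1"
  ), csv)
  expect_error(loadWorkloadTable(csv), "negative|validation")

  writeLines(c("player_id,event_index,value", "p1,0,3"), csv)
  expect_error(loadWorkloadTable(csv), "schema")

  # duplicate (player, event, variable) caught by the validity method
  rec <- data.frame(player_id = "p1", event_index = c(0L, 0L),
                    variable = "dist", value = c(1, 2))
  cal <- data.frame(event_index = 0L, date = "2024-01-01",
                    event_type = "training", md_offset = -1L)
  expect_error(seasonData(rec, cal), "duplicate")
})

test_that("a generated season round-trips through CSV exactly", {
  g <- generateSeason(emulatePaperScale("smoke_test"), seed = 4L)
  wp <- file.path(tempdir(), "season.csv")
  ip <- file.path(tempdir(), "inj.csv")
  writeSeasonCSV(g$season, wp, ip)
  back <- loadWorkloadTable(wp, injuryPath = ip)

  orig <- seasonRecords(g$season)
  got <- seasonRecords(back)
  key <- function(d) d[order(d$player_id, d$event_index, d$variable), ]
  expect_equal(key(got), key(orig), ignore_attr = TRUE)
  expect_equal(seasonCalendar(back), seasonCalendar(g$season),
               ignore_attr = TRUE)
  expect_equal(nrow(seasonInjuries(back)), nrow(seasonInjuries(g$season)))
})

test_that("buildFWF places values directly and honors the missing policy", {
  rec <- data.frame(player_id = "p1",
                    event_index = rep(0:2, 2),
                    variable = rep(c("v1", "v2"), each = 3),
                    value = c(1, 2, 3, 4, 5, 6))
  cal <- data.frame(event_index = 0:2, date = as.character(as.Date("2024-01-01") + 0:2),
                    event_type = "training", md_offset = -1L)
  season <- seasonData(rec, cal)
  fwf <- buildFWF(season, "p1", variables = c("v1", "v2"))
  expect_equal(unname(fwfValues(fwf)), rbind(c(1, 2, 3), c(4, 5, 6)))

  # drop event 1 for the player: zero_fill inserts a zero column, omit_event
  # removes it, and the two agree wherever a record exists
  season2 <- seasonData(rec[rec$event_index != 1L, ], cal)
  zf <- buildFWF(season2, "p1", missingPolicy = "zero_fill")
  oe <- buildFWF(season2, "p1", missingPolicy = "omit_event")
  expect_equal(unname(fwfValues(zf)[, 2]), c(0, 0))
  expect_equal(dim(fwfValues(oe)), c(2L, 2L))
  expect_equal(eventIndices(oe), c(0L, 2L))
  expect_equal(fwfValues(zf)[, c(1, 3)], fwfValues(oe), ignore_attr = TRUE)

  expect_error(buildFWF(season, "ghost"), "unknown player")
  expect_error(buildFWF(season, "p1", variables = "nope"), "unknown variable")
})

test_that("zero-filled footprints conserve per-variable record totals", {
  g <- generateSeason(emulatePaperScale("smoke_test"), seed = 9L)
  rec <- seasonRecords(g$season)
  for (p in seasonRoster(g$season)[1:3]) {
    fwf <- buildFWF(g$season, p, missingPolicy = "zero_fill")
    sums <- rowSums(fwfValues(fwf))
    mine <- rec[rec$player_id == p, ]
    expected <- tapply(mine$value, mine$variable, sum)
    expect_equal(sums[names(expected)], expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("injury vectors are event indicators that count the report", {
  inj <- data.frame(player_id = "p1", event_index = 4L,
                    injury_class = "muscle")
  season <- toySeason(nPlayers = 1L, nWeeks = 4L, injuries = inj)
  iv <- buildInjuryVector(season, "p1")
  expect_equal(injuryLabels(iv), as.integer(seq_len(12) - 1L == 4L))

  empty <- buildInjuryVector(toySeason(nPlayers = 1L), "p1")
  expect_true(all(injuryLabels(empty) == 0L))

  inj2 <- data.frame(player_id = c("p1", "p1"), event_index = c(2L, 8L),
                     injury_class = "muscle")
  two <- buildInjuryVector(toySeason(nPlayers = 1L, injuries = inj2), "p1")
  expect_equal(sum(injuryLabels(two)), 2L)
})

test_that("match-day labels relocate to the immediately preceding MD-1", {
  # microcycle (-2, -1, 0): matches sit at positions 3, 6, 9, 12
  inj <- data.frame(player_id = "p1", event_index = c(2L, 5L),
                    injury_class = "muscle")
  season <- toySeason(nPlayers = 1L, nWeeks = 4L, injuries = inj)
  cal <- seasonCalendar(season)
  iv <- buildInjuryVector(season, "p1")
  shifted <- shiftMatchLabelsToMD1(iv, cal)
  # both injuries were on match days (indices 2 and 5); each moves back one
  expect_equal(which(injuryLabels(shifted) == 1L) - 1L, c(1L, 4L))
  expect_equal(sum(injuryLabels(shifted)), sum(injuryLabels(iv)))

  # no match-day labels: identity
  inj3 <- data.frame(player_id = "p1", event_index = 3L,
                     injury_class = "muscle")
  season3 <- toySeason(nPlayers = 1L, injuries = inj3)
  iv3 <- buildInjuryVector(season3, "p1")
  expect_equal(injuryLabels(shiftMatchLabelsToMD1(iv3, seasonCalendar(season3))),
               injuryLabels(iv3))

  # match with a label but no MD-1 predecessor: warning and label dropped
  cal4 <- data.frame(event_index = 0:1,
                     date = as.character(as.Date("2024-01-01") + 0:1),
                     event_type = c("match", "match"), md_offset = c(0L, 0L))
  rec4 <- data.frame(player_id = "p1", event_index = 0:1, variable = "d",
                     value = 1)
  inj4 <- data.frame(player_id = "p1", event_index = 1L, injury_class = "m")
  season4 <- seasonData(rec4, cal4, injuries = inj4)
  iv4 <- buildInjuryVector(season4, "p1")
  expect_warning(out <- shiftMatchLabelsToMD1(iv4, cal4), "no MD-1")
  expect_equal(sum(injuryLabels(out)), 0L)
})

test_that("two consecutive matches each preceded by MD-1 relocate independently", {
  cal <- data.frame(event_index = 0:3,
                    date = as.character(as.Date("2024-01-01") + 0:3),
                    event_type = c("training", "match", "training", "match"),
                    md_offset = c(-1L, 0L, -1L, 0L))
  rec <- data.frame(player_id = "p1", event_index = 0:3, variable = "d",
                    value = 1)
  inj <- data.frame(player_id = c("p1", "p1"), event_index = c(1L, 3L),
                    injury_class = "m")
  season <- seasonData(rec, cal, injuries = inj)
  shifted <- shiftMatchLabelsToMD1(buildInjuryVector(season, "p1"), cal)
  expect_equal(injuryLabels(shifted), c(1L, 0L, 1L, 0L))
})

test_that("participation is inferred from record presence", {
  season <- toySeason(nPlayers = 2L, nWeeks = 2L,
                      benched = data.frame(player_id = "p2", event_index = 3L))
  part <- participationMatrix(season)
  expect_true(all(part["p1", ]))
  expect_false(part["p2", "3"])
  expect_true(part["p2", "2"])
})
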