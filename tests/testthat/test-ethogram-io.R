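test_that("a minimal well-formed table parses into one observation", {
  rows <- dplyr::bind_rows(
    evt_row("a1", "contact", 0, 0),
    evt_row("a1", "paralyze", 1.5, 3.0))
  res <- parse_event_table(rows)
  expect_length(res$observations, 1)
  expect_equal(res$report$n_accepted, 1)
  expect_equal(nrow(res$observations[[1]]$events), 2)
  expect_equal(res$observations[[1]]$events$step, c("contact", "paralyze"))
})

test_that("grammar violations and malformed rows are rejected and reported", {
  rows <- dplyr::bind_rows(
    # bend without tcr: sequence grammar violation
    evt_row("bad1", "contact", 0, 0),
    evt_row("bad1", "paralyze", 1, 2),
    evt_row("bad1", "bend", 5, 6),
    # row-level problems
    evt_row("bad2", "munch", 1, 2),
    evt_row("bad2", "contact", 0, 0),
    evt_row("bad3", "contact", 0, 0),
    evt_row("bad3", "tcr", 5, 4),
    # duplicate step
    evt_row("bad4", "contact", 0, 0),
    evt_row("bad4", "paralyze", 1, 2),
    evt_row("bad4", "paralyze", 3, 4),
    # a good one
    evt_row("ok", "contact", 0, 0),
    evt_row("ok", "paralyze", 1, 2),
    evt_row("ok", "tcr", 4, 6))
  res <- parse_event_table(rows)
  ids <- vapply(res$observations, `[[`, character(1), "observation_id")
  expect_setequal(ids, c("ok", "bad2", "bad3"))
  expect_equal(res$report$n_rejected_rows, 2)
  expect_gte(res$report$n_rejected_observations, 2)
  expect_true(any(grepl("grammar", res$report$rejections$reason)))
  expect_true(any(grepl("duplicate", res$report$rejections$reason)))
  expect_true(any(grepl("unknown step", res$report$rejections$reason)))
})

test_that("round-trip through the CSV dialect preserves structures", {
  d <- simulate_dataset("fed", n_subjects = 5, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(d$observations, path)
  back <- read_event_table(path)
  expect_equal(back$report$n_accepted, length(d$observations))
  expect_equal(back$report$n_rejected_rows, 0)
  # identical structures after the round trip (event times to within
  # text-representation precision)
  expect_equal(extract_timings_all(back$observations),
               extract_timings_all(d$observations), tolerance = 1e-12)
  for (i in seq_along(d$observations)) {
    expect_equal(back$observations[[i]]$events, d$observations[[i]]$events,
                 tolerance = 1e-12)
    expect_identical(back$observations[[i]]$condition,
                     d$observations[[i]]$condition)
  }
})

test_that("timing extraction implements the ISI and censoring definitions", {
  obs <- obs_from_times(paralyze = c(4, 4), tcr = c(9, 11.5))
  t <- extract_timings(obs)
  # paralyze latency runs from contact to paralysis completion
  expect_equal(t$latency_s[t$step == "paralyze"], 4)
  expect_false(t$censored[t$step == "paralyze"])
  # TCR ISI runs from paralysis completion to TCR onset
  expect_equal(t$latency_s[t$step == "tcr"], 5)
  expect_equal(t$duration_s[t$step == "tcr"], 2.5)
  # unexecuted downstream steps are right-censored at the window
  expect_true(all(t$censored[t$step %in% c("bend", "ingest")]))
  expect_true(all(t$latency_s[t$step %in% c("bend", "ingest")] == 120))

  # paralyze executed, nothing after, custom window
  obs2 <- obs_from_times(paralyze = c(3, 3), window = 60)
  t2 <- extract_timings(obs2)
  expect_equal(t2$latency_s[t2$step == "tcr"], 60)
  expect_true(t2$censored[t2$step == "tcr"])
})

test_that("timing extraction enforces the window bound and counts events", {
  d <- simulate_dataset("fed", n_subjects = 30, seed = 11)
  tim <- extract_timings_all(d$observations)
  expect_true(all(tim$latency_s <= 120))
  # executed steps and uncensored records are the same thing
  n_executed <- sum(vapply(d$observations, function(o) {
    nrow(o$events) - 1L
  }, integer(1)))
  expect_equal(sum(!tim$censored), n_executed)
  # grammar: executed ranks form a prefix of the canonical order
  for (o in d$observations) {
    r <- sort(step_rank(o$events$step))
    expect_identical(r, seq_along(r) - 1L)
  }
})

test_that("overlapping annotations produce a named negative-ISI error", {
  # bend starts before the TCR offset: onsets are ordered but the bend ISI
  # is negative
  obs <- obs_from_times(paralyze = c(3, 3), tcr = c(5, 10), bend = c(8, 12))
  expect_error(extract_timings(obs), "bend")
})

test_that("condition filtering subsets without reordering", {
  mixed <- c(simulate_dataset("starved", n_subjects = 2, seed = 1)$observations,
             simulate_dataset("fed", n_subjects = 2, seed = 1)$observations)
  st <- filter_observations(mixed, feeding_state = "starved")
  expect_length(st, 10)
  expect_identical(filter_observations(mixed), mixed)
  expect_error(filter_observations(mixed, diet = "starved"), "Unknown")
  # time-course arm selection matches the generator's bookkeeping
  tc <- c(simulate_dataset("fed_tc_5", n_subjects = 4, seed = 2)$observations,
          simulate_dataset("fed_tc_30", n_subjects = 3, seed = 2)$observations)
  arm5 <- filter_observations(tc, minutes_since_meal = 5)
  expect_length(arm5, 4)
  expect_true(all(vapply(arm5, function(o) {
    o$condition$minutes_since_meal == 5L
  }, logical(1))))
})
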