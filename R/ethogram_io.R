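#' Condition label for an observation
#'
#' Encodes the experimental condition of a prey-offer episode: the animal's
#' feeding state, the preparation (intact animal, manubrium-less animal, or
#' a tentacle severed above/below the ocellus-containing bulb), whether the
#' tentacle had previously been used for feeding, and — for the satiety
#' time course — the number of minutes elapsed since a brief meal.
#'
#' @param feeding_state `"starved"` or `"fed"`.
#' @param preparation One of `"intact"`, `"manubrium_less"`,
#'   `"tentacle_above_bulb"`, `"tentacle_below_bulb"`.
#' @param tentacle_use One of `"na"`, `"used"`, `"unused"` (used/unused only
#'   meaningful for the tentacle-targeting experiment).
#' @param minutes_since_meal Integer in `{5, 10, 30, 60}` for the post-meal
#'   time course, or `NA`. Only allowed when `feeding_state = "fed"`.
#' @return A named list of class `"condition_label"`.
#' @export
condition_label <- function(feeding_state = "starved",
                            preparation = "intact",
                            tentacle_use = "na",
                            minutes_since_meal = NA_integer_) {
  feeding_state <- match.arg(feeding_state, c("starved", "fed"))
  preparation <- match.arg(preparation,
                           c("intact", "manubrium_less",
                             "tentacle_above_bulb", "tentacle_below_bulb"))
  tentacle_use <- match.arg(tentacle_use, c("na", "used", "unused"))
  if (!is.na(minutes_since_meal)) {
    minutes_since_meal <- as.integer(minutes_since_meal)
    if (!minutes_since_meal %in% c(5L, 10L, 30L, 60L)) {
      stop("minutes_since_meal must be NA or one of 5, 10, 30, 60")
    }
    if (feeding_state != "fed") {
      stop("minutes_since_meal can only be set for fed animals")
    }
  } else {
    minutes_since_meal <- NA_integer_
  }
  structure(list(feeding_state = feeding_state,
                 preparation = preparation,
                 tentacle_use = tentacle_use,
                 minutes_since_meal = minutes_since_meal),
            class = "condition_label")
}

condition_fields <- function() {
  c("feeding_state", "preparation", "tentacle_use", "minutes_since_meal")
}

#' A single prey-offer observation
#'
#' One episode of prey offered to one animal or tentacle preparation:
#' an ordered set of behavioral events (step, onset, optional offset, in
#' seconds relative to prey contact at t = 0) under one condition, observed
#' with a per-step censoring window.
#'
#' Sequence grammar: contact is always present at t = 0, at most one event
#' per canonical step, and a step of rank r requires all steps of lower
#' rank. `observation()` enforces these invariants.
#'
#' @param observation_id,subject_id Opaque identifier strings.
#' @param condition A [condition_label()].
#' @param events Data frame with columns `step`, `onset_s`, `offset_s`
#'   (NA offset = instantaneous annotation). A contact row at t = 0 is
#'   added if absent.
#' @param window_s Censoring horizon in seconds, applied per step from its
#'   timing reference (default 120: two minutes were allowed for each step).
#' @param validate Set `FALSE` to skip invariant checks for inputs known to
#'   be well-formed (used internally by the simulator).
#' @return An object of class `"observation"`.
#' @export
observation <- function(observation_id, subject_id, condition, events,
                        window_s = 120, validate = TRUE) {
  events <- as.data.frame(events)[, c("step", "onset_s", "offset_s")]
  events$step <- as.character(events$step)
  events$onset_s <- as.numeric(events$onset_s)
  events$offset_s <- as.numeric(events$offset_s)
  if (!"contact" %in% events$step) {
    events <- rbind(data.frame(step = "contact", onset_s = 0, offset_s = 0),
                    events)
  }
  events <- events[order(step_rank(events$step)), , drop = FALSE]
  rownames(events) <- NULL
  obs <- structure(list(observation_id = as.character(observation_id),
                        subject_id = as.character(subject_id),
                        condition = condition,
                        events = events,
                        window_s = window_s),
                   class = "observation")
  if (validate) {
    msg <- validate_observation(obs)
    if (!is.null(msg)) stop("Invalid observation '", observation_id, "': ", msg)
  }
  obs
}

#' Validate the sequence grammar and timing invariants of an observation
#'
#' @param obs An [observation()].
#' @return `NULL` if valid, otherwise a character string describing the
#'   first violation found.
#' @export
validate_observation <- function(obs) {
  ev <- obs$events
  bad <- !ev$step %in% feeding_steps()
  if (any(bad)) return(paste0("unknown step label: ", ev$step[bad][1]))
  if (anyDuplicated(ev$step)) {
    return(paste0("duplicate step: ", ev$step[duplicated(ev$step)][1]))
  }
  if (!inherits(obs$condition, "condition_label")) {
    return("condition is not a condition_label")
  }
  con <- ev[ev$step == "contact", ]
  if (nrow(con) != 1 || con$onset_s != 0) {
    return("contact must be present at t = 0")
  }
  if (any(is.na(ev$onset_s)) || any(ev$onset_s < 0)) {
    return("onsets must be non-negative seconds")
  }
  off_ok <- is.na(ev$offset_s) | ev$offset_s >= ev$onset_s
  if (!all(off_ok)) {
    return(paste0("offset before onset for step ", ev$step[!off_ok][1]))
  }
  ranks <- sort(step_rank(ev$step))
  if (!identical(ranks, seq_along(ranks) - 1L)) {
    executed <- feeding_steps()[ranks + 1L]
    missing <- setdiff(feeding_steps()[seq_len(max(ranks) + 1L)], executed)
    return(paste0("sequence grammar violated: ",
                  paste(missing, collapse = ", "),
                  " missing before ", feeding_steps()[max(ranks) + 1L]))
  }
  if (is.unsorted(ev$onset_s)) return("events out of temporal order")
  NULL
}

#' @export
print.observation <- function(x, ...) {
  cat("<observation>", x$observation_id,
      sprintf("(subject %s, %s/%s)", x$subject_id,
              x$condition$feeding_state, x$condition$preparation), "\n")
  print(x$events)
  invisible(x)
}

#' Parse a long-format behavioral event table
#'
#' Reads one row per behavioral event (observation and subject identity,
#' condition columns, step name, onset and offset seconds) and assembles
#' grammar-validated [observation()] objects. Rows and observations that
#' violate the schema or the sequence grammar are rejected, never silently
#' repaired, and reported.
#'
#' Expected columns: `observation_id`, `subject_id`, `feeding_state`,
#' `preparation`, `tentacle_use`, `minutes_since_meal`, `step`, `onset_s`,
#' `offset_s` (empty cell = absent offset).
#'
#' @param rows A data frame in the event-table dialect.
#' @param window_s Censoring horizon per step, seconds.
#' @return A list with `observations` (list of [observation()]) and
#'   `report`: counts of accepted observations, rejected rows and rejected
#'   observations, plus a tibble of rejection reasons.
#' @export
parse_event_table <- function(rows, window_s = 120) {
  rows <- tibble::as_tibble(rows)
  needed <- c("observation_id", "subject_id", condition_fields(),
              "step", "onset_s", "offset_s")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0) {
    stop("Event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(rows) == 0) stop("Event table has no rows")

  rows$onset_s <- suppressWarnings(as.numeric(rows$onset_s))
  rows$offset_s <- suppressWarnings(as.numeric(rows$offset_s))

  rejections <- list()
  reject <- function(id, level, reason) {
    tibble::tibble(observation_id = id, level = level, reason = reason)
  }

  # row-level screening
  bad_step <- !rows$step %in% feeding_steps()
  bad_onset <- is.na(rows$onset_s) | rows$onset_s < 0
  bad_offset <- !is.na(rows$offset_s) & rows$offset_s < rows$onset_s
  row_bad <- bad_step | bad_onset | bad_offset
  if (any(row_bad)) {
    reason <- ifelse(bad_step, "unknown step label",
                     ifelse(bad_onset, "missing or negative onset",
                            "offset before onset"))
    rejections <- c(rejections, list(
      reject(rows$observation_id[row_bad], "row", reason[row_bad])))
  }
  n_rejected_rows <- sum(row_bad)
  rows <- rows[!row_bad, , drop = FALSE]

  obs_list <- list()
  n_rejected_obs <- 0L
  for (id in unique(rows$observation_id)) {
    sub <- rows[rows$observation_id == id, , drop = FALSE]
    cond_cols <- unique(sub[, c("subject_id", condition_fields())])
    if (nrow(cond_cols) > 1) {
      rejections <- c(rejections, list(
        reject(id, "observation", "inconsistent subject/condition fields")))
      n_rejected_obs <- n_rejected_obs + 1L
      next
    }
    if (anyDuplicated(sub$step)) {
      rejections <- c(rejections, list(
        reject(id, "observation",
               paste0("duplicate step: ", sub$step[duplicated(sub$step)][1]))))
      n_rejected_obs <- n_rejected_obs + 1L
      next
    }
    cond <- tryCatch(
      condition_label(
        feeding_state = as.character(cond_cols$feeding_state),
        preparation = as.character(cond_cols$preparation),
        tentacle_use = as.character(cond_cols$tentacle_use),
        minutes_since_meal = cond_cols$minutes_since_meal),
      error = function(e) conditionMessage(e))
    if (is.character(cond)) {
      rejections <- c(rejections, list(reject(id, "observation", cond)))
      n_rejected_obs <- n_rejected_obs + 1L
      next
    }
    obs <- tryCatch(
      observation(id, cond_cols$subject_id, cond,
                  sub[, c("step", "onset_s", "offset_s")],
                  window_s = window_s),
      error = function(e) conditionMessage(e))
    if (is.character(obs)) {
      rejections <- c(rejections, list(reject(id, "observation", obs)))
      n_rejected_obs <- n_rejected_obs + 1L
      next
    }
    obs_list[[id]] <- obs
  }

  rejections <- if (length(rejections) > 0) {
    dplyr::bind_rows(rejections)
  } else {
    tibble::tibble(observation_id = character(), level = character(),
                   reason = character())
  }
  list(observations = unname(obs_list),
       report = list(n_accepted = length(obs_list),
                     n_rejected_rows = n_rejected_rows,
                     n_rejected_observations = n_rejected_obs,
                     rejections = rejections))
}

#' Write observations back to the long event-table dialect
#'
#' The inverse of [parse_event_table()]: round-tripping a parsed set of
#' observations through `write_event_table()` and back reproduces the same
#' structures.
#'
#' @param observations List of [observation()] objects.
#' @param path Optional CSV path; when given the table is written there.
#' @return The event tibble, invisibly when `path` is given.
#' @export
write_event_table <- function(observations, path = NULL) {
  tabs <- lapply(observations, function(obs) {
    ev <- obs$events
    tibble::tibble(
      observation_id = obs$observation_id,
      subject_id = obs$subject_id,
      feeding_state = obs$condition$feeding_state,
      preparation = obs$condition$preparation,
      tentacle_use = obs$condition$tentacle_use,
      minutes_since_meal = obs$condition$minutes_since_meal,
      step = ev$step,
      onset_s = ev$onset_s,
      offset_s = ev$offset_s)
  })
  tab <- dplyr::bind_rows(tabs)
  if (!is.null(path)) {
    readr::write_csv(tab, path, na = "")
    return(invisible(tab))
  }
  tab
}

#' @rdname parse_event_table
#' @param path CSV file in the event-table dialect (UTF-8, header row).
#' @export
read_event_table <- function(path, window_s = 120) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           observation_id = readr::col_character(),
                           subject_id = readr::col_character(),
                           feeding_state = readr::col_character(),
                           preparation = readr::col_character(),
                           tentacle_use = readr::col_character(),
                           minutes_since_meal = readr::col_integer(),
                           step = readr::col_character(),
                           onset_s = readr::col_double(),
                           offset_s = readr::col_double()))
  parse_event_table(tab, window_s = window_s)
}

#' Extract per-step timing records from an observation
#'
#' Computes, for each timed step, its latency from the step's timing
#' reference and, where defined, its duration:
#' * paralyze: latency = time from prey contact to paralysis completion
#'   (this quantity is the paper-style "paralyze duration" t1; no separate
#'   duration is recorded),
#' * tcr / bend / ingest: latency = inter-step interval (ISI) from the
#'   preceding step's offset to this step's onset; duration = offset - onset.
#'
#' A step not executed within `window_s` of its timing reference (including
#' every step downstream of a failure) yields a right-censored record with
#' `latency_s = window_s` and no duration.
#'
#' @param obs A grammar-valid [observation()].
#' @return Tibble with columns `observation_id`, `step`, `latency_s`,
#'   `duration_s`, `censored`.
#' @export
extract_timings <- function(obs) {
  core <- timings_core(obs)
  tibble::tibble(observation_id = obs$observation_id, step = timed_steps(),
                 latency_s = core$latency, duration_s = core$duration,
                 censored = core$censored)
}

# internal vectorized core of extract_timings (no tibble allocation), used
# by the per-observation wrapper, extract_timings_all and occurrence_matrix
timings_core <- function(obs) {
  ev <- obs$events
  window <- obs$window_s
  steps <- timed_steps()
  lat_out <- rep(window, 4)
  dur_out <- rep(NA_real_, 4)
  cens_out <- rep(TRUE, 4)
  ref <- 0 # timing reference: contact at t = 0
  idx <- match(steps, ev$step)
  for (i in 1:4) {
    st <- steps[i]
    j <- idx[i]
    if (is.na(j)) break # absent step censors itself and everything after
    onset <- ev$onset_s[j]
    offset <- ev$offset_s[j]
    end <- if (is.na(offset)) onset else offset
    if (st == "paralyze") {
      # latency runs to paralysis completion; the completion time point is
      # the annotation, so no separate duration exists for this step
      lat <- end - ref
      dur <- NA_real_
    } else {
      lat <- onset - ref
      dur <- if (is.na(offset)) NA_real_ else offset - onset
    }
    if (lat < 0) {
      stop("Negative inter-step interval in observation '", obs$observation_id,
           "': ", st, " onset precedes the preceding step's offset")
    }
    # executed outside the horizon: scored as not occurring within the
    # window, which censors this and every downstream step
    if (lat > window) break
    lat_out[i] <- lat
    dur_out[i] <- dur
    cens_out[i] <- FALSE
    ref <- end
  }
  list(latency = lat_out, duration = dur_out, censored = cens_out)
}

#' @rdname extract_timings
#' @param observations List of observations; timings are stacked and the
#'   condition columns attached for grouped analysis.
#' @export
extract_timings_all <- function(observations) {
  n <- length(observations)
  cores <- lapply(observations, timings_core)
  each <- function(f) vapply(observations, f, character(1))
  tibble::tibble(
    observation_id = rep(each(function(o) o$observation_id), each = 4),
    step = rep(timed_steps(), times = n),
    latency_s = unlist(lapply(cores, `[[`, "latency"), use.names = FALSE),
    duration_s = unlist(lapply(cores, `[[`, "duration"), use.names = FALSE),
    censored = unlist(lapply(cores, `[[`, "censored"), use.names = FALSE),
    subject_id = rep(each(function(o) o$subject_id), each = 4),
    feeding_state = rep(each(function(o) o$condition$feeding_state),
                        each = 4),
    preparation = rep(each(function(o) o$condition$preparation), each = 4),
    tentacle_use = rep(each(function(o) o$condition$tentacle_use), each = 4),
    minutes_since_meal = rep(vapply(observations, function(o) {
      o$condition$minutes_since_meal
    }, integer(1)), each = 4))
}

#' Subset observations by condition
#'
#' Order-preserving filter over condition fields. Arguments are matched by
#' name against the condition label; an unknown field is an error. With no
#' filter arguments the input list is returned unchanged.
#'
#' @param observations List of [observation()] objects.
#' @param ... Named condition values, e.g. `feeding_state = "starved"`,
#'   `minutes_since_meal = 5`. `NA` matches records where the field is
#'   absent.
#' @param quiet Suppress the selection message.
#' @return Filtered list of observations.
#' @export
filter_observations <- function(observations, ..., quiet = TRUE) {
  crit <- list(...)
  if (length(crit) == 0) return(observations)
  unknown <- setdiff(names(crit), condition_fields())
  if (length(unknown) > 0 || is.null(names(crit)) || any(names(crit) == "")) {
    stop("Unknown condition field(s): ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         ". Valid fields: ", paste(condition_fields(), collapse = ", "))
  }
  keep <- vapply(observations, function(obs) {
    all(vapply(names(crit), function(f) {
      want <- crit[[f]]
      have <- obs$condition[[f]]
      if (is.na(want)) is.na(have) else (!is.na(have) && have == want)
    }, logical(1)))
  }, logical(1))
  if (!quiet) {
    message("filter_observations: kept ", sum(keep), " of ",
            length(observations), " observations")
  }
  observations[keep]
}

#' Step occurrence within the observation window
#'
#' @param observations List of observations.
#' @param steps Steps to score (default all timed steps).
#' @return Logical matrix, one row per observation, `TRUE` where the step
#'   was executed within its censoring window.
#' @export
occurrence_matrix <- function(observations, steps = timed_steps()) {
  want <- match(steps, timed_steps())
  m <- vapply(observations, function(obs) {
    !timings_core(obs)$censored[want]
  }, logical(length(steps)))
  m <- if (is.null(dim(m))) matrix(m, ncol = 1) else t(m)
  colnames(m) <- steps
  rownames(m) <- vapply(observations, `[[`, character(1), "observation_id")
  m
}

#' Validate an exported copy of the deposited raw-data tables
#'
#' Reads event-table CSVs (`starved.csv`, `fed.csv`, in the
#' [parse_event_table()] dialect) from a local directory holding an export
#' of the study's public raw-data deposit, and returns the accepted
#' observation counts per file for comparison against the reported ns.
#'
#' @param dir Directory containing the exported CSV files.
#' @return Named integer vector of accepted observation counts.
#' @export
validate_deposit <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("No CSV files found under ", dir)
  counts <- vapply(files, function(f) {
    parse_event_table(readr::read_csv(f, show_col_types = FALSE))$report$n_accepted
  }, integer(1))
  names(counts) <- sub("\\.csv$", "", basename(files))
  counts
}
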