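#' Censored latency sample for one step
#'
#' Collects the (time, event-observed) pairs for one feeding step from a
#' timing table, for Kaplan-Meier analysis. Censored records carry
#' `latency_s = window_s` and `observed = FALSE`.
#'
#' @param timings Tibble from [extract_timings_all()] (or
#'   [extract_timings()]).
#' @param step The step whose latency (paralyze completion time or ISI) is
#'   analyzed.
#' @param quantity `"latency"` or `"duration"`. Durations exist only for
#'   executed tcr/bend/ingest and are never censored; censored rows are
#'   dropped for `"duration"`.
#'
#' @details A step's latency clock only starts when its timing reference
#' exists, so the sample conditions on the preceding step having been
#' executed: observations that already failed upstream are excluded rather
#' than censored (this is why per-step sample sizes shrink along the
#' sequence). The step's own failure within its window is a right-censored
#' record at `window_s`.
#' @return Object of class `"latency_sample"` with `times_s`, `observed`,
#'   `n`.
#' @export
latency_sample <- function(timings, step, quantity = c("latency", "duration")) {
  quantity <- match.arg(quantity)
  step <- match.arg(step, timed_steps())
  sub <- timings[timings$step == step, , drop = FALSE]
  r <- match(step, timed_steps())
  if (r > 1) {
    prev <- timed_steps()[r - 1]
    prev_ok <- timings$observation_id[timings$step == prev &
                                        !timings$censored]
    sub <- sub[sub$observation_id %in% prev_ok, , drop = FALSE]
  }
  if (quantity == "latency") {
    times <- sub$latency_s
    observed <- !sub$censored
  } else {
    sub <- sub[!sub$censored & !is.na(sub$duration_s), , drop = FALSE]
    times <- sub$duration_s
    observed <- rep(TRUE, nrow(sub))
  }
  structure(list(step = step, quantity = quantity,
                 times_s = as.numeric(times), observed = observed,
                 n = length(times)),
            class = "latency_sample")
}

#' Kaplan-Meier cumulative-fraction curve
#'
#' Product-limit estimate of the fraction of observations having executed a
#' step by time t, reported as the cumulative fraction 1 - S(t). With
#' right-censoring by the observation window the curve may plateau below 1
#' (never-responders). Percentile times T25/T50/T75 are the first event
#' times at which the cumulative fraction reaches 0.25/0.50/0.75, with no
#' interpolation; a percentile the curve never reaches is `NA`
#' ("not reached").
#'
#' @param sample A [latency_sample()].
#' @return Object of class `"km_curve"`: `time` (increasing event times),
#'   `cum_fraction`, `at_risk`, `n_events`, `n`, and `percentiles` (named
#'   numeric for 25/50/75, `NA` = not reached).
#' @export
km_curve <- function(sample) {
  stopifnot(inherits(sample, "latency_sample"))
  if (sample$n < 1) stop("Empty latency sample")
  if (!any(sample$observed)) {
    warning("All observations censored: curve is flat at 0, ",
            "all percentiles not reached")
    return(structure(list(time = numeric(0), cum_fraction = numeric(0),
                          at_risk = integer(0), n_events = 0L, n = sample$n,
                          percentiles = c(`25` = NA_real_, `50` = NA_real_,
                                          `75` = NA_real_)),
                     class = "km_curve"))
  }
  fit <- survival::survfit(
    survival::Surv(sample$times_s, sample$observed) ~ 1,
    conf.type = "none")
  keep <- fit$n.event > 0
  time <- fit$time[keep]
  cum <- 1 - fit$surv[keep]
  at_risk <- fit$n.risk[keep]
  pct <- vapply(c(25, 50, 75), function(q) {
    hit <- which(cum >= q / 100 - 1e-12)
    if (length(hit) == 0) NA_real_ else time[min(hit)]
  }, numeric(1))
  names(pct) <- c("25", "50", "75")
  structure(list(time = time, cum_fraction = cum,
                 at_risk = as.integer(at_risk),
                 n_events = as.integer(sum(fit$n.event)),
                 n = sample$n, percentiles = pct),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d\n", x$n, x$n_events))
  cat("  T25/T50/T75 (s):",
      paste(ifelse(is.na(x$percentiles), "not reached", x$percentiles),
            collapse = " / "), "\n")
  invisible(x)
}

#' Tidy a set of Kaplan-Meier curves
#'
#' @param curves Named list of `km_curve`s; names become the condition
#'   column.
#' @param step Step label to attach.
#' @return Tibble (condition, step, time, cum_fraction, at_risk).
#' @export
km_tidy <- function(curves, step = NA_character_) {
  dplyr::bind_rows(lapply(names(curves), function(cond) {
    k <- curves[[cond]]
    tibble::tibble(condition = cond, step = step, time = k$time,
                   cum_fraction = k$cum_fraction, at_risk = k$at_risk)
  }))
}

#' Log-rank (Mantel-Cox) test between censored latency samples
#'
#' Two-group Mantel-Cox statistic with 1 df; with k > 2 samples the
#' k-group variant with k - 1 df (used for the post-meal time course).
#' Two-sided p from the upper chi-square tail.
#'
#' @param ... Two or more [latency_sample()] objects, or a single list of
#'   them.
#' @return List with `chi_square`, `df`, `p_two_sided`, `n`.
#' @export
logrank_test <- function(...) {
  samples <- list(...)
  if (length(samples) == 1 && !inherits(samples[[1]], "latency_sample")) {
    samples <- samples[[1]]
  }
  if (length(samples) < 2) stop("Need at least two latency samples")
  if (any(vapply(samples, function(s) s$n, integer(1)) == 0)) {
    stop("Empty latency sample supplied")
  }
  times <- unlist(lapply(samples, `[[`, "times_s"))
  observed <- unlist(lapply(samples, `[[`, "observed"))
  group <- rep(seq_along(samples),
               vapply(samples, function(s) s$n, integer(1)))
  df <- length(samples) - 1L
  if (!any(observed)) {
    warning("No events in any group; log-rank statistic is 0")
    return(list(chi_square = 0, df = df, p_two_sided = 1,
                n = length(times)))
  }
  sd <- survival::survdiff(survival::Surv(times, observed) ~ group, rho = 0)
  chi <- unname(sd$chisq)
  list(chi_square = chi, df = df,
       p_two_sided = stats::pchisq(chi, df = df, lower.tail = FALSE),
       n = length(times))
}

#' Fold change of median (T50) times between conditions
#'
#' Ratio of the Kaplan-Meier T50 of the first sample to that of the second
#' (conventionally fed over starved, so values above 1 mean satiety slowed
#' the step). When either curve never reaches its median the ratio is
#' undefined and returned as `NA` with a reason, never as infinity.
#'
#' @param sample_num,sample_den [latency_sample()]s for numerator and
#'   denominator conditions.
#' @return List with `ratio` (`NA` if undefined), `t50_num`, `t50_den`,
#'   `reason` (`NULL` when defined).
#' @export
t50_fold_change <- function(sample_num, sample_den) {
  t50 <- function(s) suppressWarnings(km_curve(s))$percentiles[["50"]]
  num <- t50(sample_num)
  den <- t50(sample_den)
  if (is.na(num) || is.na(den)) {
    which_na <- c("numerator", "denominator")[c(is.na(num), is.na(den))]
    return(list(ratio = NA_real_, t50_num = num, t50_den = den,
                reason = paste("T50 not reached in",
                               paste(which_na, collapse = " and "),
                               "sample")))
  }
  list(ratio = num / den, t50_num = num, t50_den = den, reason = NULL)
}

#' Rank correlation between timing quantities of adjacent steps
#'
#' Spearman correlation between two timing quantities (latency/ISI or
#' duration) across observations where both are uncensored. Used to check
#' that the timings of adjacent feeding steps are independently controlled.
#'
#' @param timings Tibble from [extract_timings_all()].
#' @param step_a,step_b The two steps.
#' @param quantity_a,quantity_b `"latency"` or `"duration"` for each step.
#' @return List with `rho`, `p`, `n_pairs`.
#' @export
adjacent_timing_correlation <- function(timings, step_a, step_b,
                                        quantity_a = "latency",
                                        quantity_b = "latency") {
  pick <- function(step, quantity) {
    sub <- timings[timings$step == step & !timings$censored, , drop = FALSE]
    v <- if (quantity == "latency") sub$latency_s else sub$duration_s
    stats::setNames(v, sub$observation_id)[!is.na(v)]
  }
  a <- pick(step_a, match.arg(quantity_a, c("latency", "duration")))
  b <- pick(step_b, match.arg(quantity_b, c("latency", "duration")))
  ids <- intersect(names(a), names(b))
  if (length(ids) < 3) {
    stop("Fewer than 3 paired uncensored records for ",
         step_a, " vs ", step_b)
  }
  ct <- suppressWarnings(
    stats::cor.test(a[ids], b[ids], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(ids))
}
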