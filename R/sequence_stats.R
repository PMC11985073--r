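#' First-order transition table from one feeding step
#'
#' For every observation that executed `from_step` within its window, the
#' outcome is the next canonical step executed afterwards, or `"none"` when
#' no further behavior occurred within the window. Outcomes keep skip-ahead
#' transitions (e.g. paralyze -> bend without TCR) in their own columns;
#' collapsing is a rendering choice, not a data operation.
#'
#' @param observations List of [observation()] objects.
#' @param from_step Step whose outgoing transitions are counted.
#' @return Object of class `"transition_table"`: outcome labels, integer
#'   counts, `n`, probabilities (counts / n), plus the number of
#'   observations excluded because they never executed `from_step`.
#' @export
transition_matrix <- function(observations, from_step) {
  from_step <- match.arg(from_step, feeding_steps()[-5])
  occ <- occurrence_matrix(observations)
  executed_from <- if (from_step == "contact") {
    rep(TRUE, length(observations))
  } else {
    occ[, from_step]
  }
  n_excluded <- sum(!executed_from)
  if (sum(executed_from) == 0) {
    stop("No observations executed step '", from_step,
         "'; cannot form a transition table")
  }
  later <- steps_after(from_step)
  outcomes <- c(later, "none")
  occ_later <- occ[executed_from, later, drop = FALSE]
  outcome_of <- apply(occ_later, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) "none" else later[min(hit)]
  })
  counts <- table(factor(outcome_of, levels = outcomes))
  n <- sum(counts)
  structure(list(from_step = from_step,
                 outcomes = outcomes,
                 counts = as.integer(counts),
                 n = as.integer(n),
                 probabilities = as.numeric(counts) / n,
                 n_excluded = as.integer(n_excluded)),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> from %s (n = %d, %d excluded)\n",
              x$from_step, x$n, x$n_excluded))
  print(stats::setNames(round(x$probabilities, 3), x$outcomes))
  invisible(x)
}

#' Tidy a set of transition tables
#'
#' @param tables Named list of `transition_table`s (names used as the
#'   condition column).
#' @return Tibble with columns condition, from_step, outcome, count,
#'   probability, n.
#' @export
transition_tidy <- function(tables) {
  conds <- names(tables)
  if (is.null(conds)) conds <- as.character(seq_along(tables))
  dplyr::bind_rows(lapply(seq_along(tables), function(i) {
    tt <- tables[[i]]
    tibble::tibble(condition = conds[i], from_step = tt$from_step,
                   outcome = tt$outcomes, count = tt$counts,
                   probability = tt$probabilities, n = tt$n)
  }))
}

#' Collapse two transition tables to a 2x2 contingency table
#'
#' Reduces each condition's outcomes to canonical-next vs everything else
#' (the minimal faithful reduction for a Fisher's exact comparison of the
#' dominant transition between conditions). The full r x c table is
#' available via `transition_rxc()` for a chi-square comparison.
#'
#' @param table_a,table_b `transition_table`s with the same `from_step`.
#' @param labels Row labels for the two conditions.
#' @return 2x2 integer matrix (rows = conditions, cols = next / other).
#' @export
transition_2x2 <- function(table_a, table_b, labels = c("a", "b")) {
  if (table_a$from_step != table_b$from_step) {
    stop("Transition tables have different from_steps")
  }
  nxt <- next_step(table_a$from_step)
  row_of <- function(tt) {
    k <- tt$counts[match(nxt, tt$outcomes)]
    c(k, tt$n - k)
  }
  m <- rbind(row_of(table_a), row_of(table_b))
  dimnames(m) <- list(labels, c(nxt, "other"))
  m
}

#' @rdname transition_2x2
#' @export
transition_rxc <- function(table_a, table_b, labels = c("a", "b")) {
  if (!identical(table_a$outcomes, table_b$outcomes)) {
    stop("Transition tables have different outcome alphabets")
  }
  m <- rbind(table_a$counts, table_b$counts)
  dimnames(m) <- list(labels, table_a$outcomes)
  m
}

#' Agreement probability between a tentacle-mediated step and ingestion
#'
#' Fraction of observations in which the step and ingestion either both
#' occurred or both failed within the observation window. Censored
#' observations score as failure of the step, matching occurrence scoring
#' within the observation period.
#'
#' @param observations List of observations.
#' @param step One of `"paralyze"`, `"tcr"`, `"bend"`.
#' @return Object of class `"agreement_result"`: `step`, `n`,
#'   `n_concordant`, `probability`, and the underlying 2x2 occurrence
#'   `table` (step occurrence x ingestion occurrence) for downstream
#'   testing.
#' @export
agreement_probability <- function(observations, step) {
  step <- match.arg(step, c("paralyze", "tcr", "bend"))
  if (length(observations) == 0) stop("No observations supplied")
  occ <- occurrence_matrix(observations, steps = c(step, "ingest"))
  concordant <- occ[, 1] == occ[, 2]
  tab <- table(factor(occ[, 1], levels = c(FALSE, TRUE),
                      labels = c("step_fail", "step_occur")),
               factor(occ[, 2], levels = c(FALSE, TRUE),
                      labels = c("ingest_fail", "ingest_occur")))
  structure(list(step = step,
                 n = nrow(occ),
                 n_concordant = sum(concordant),
                 probability = mean(concordant),
                 table = unclass(tab)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s vs ingestion: %.3f (%d/%d)\n",
              x$step, x$probability, x$n_concordant, x$n))
  invisible(x)
}

#' Prey consumption per subject
#'
#' Groups observations by subject and counts ingestion successes out of the
#' offers made to that subject (the protocol offers 5 brine shrimps
#' sequentially to each intact animal).
#'
#' @param observations List of observations.
#' @return Tibble with `subject_id`, `feeding_state`, `offered`, `consumed`.
#' @export
consumption_counts <- function(observations) {
  if (length(observations) == 0) stop("No observations supplied")
  occ <- occurrence_matrix(observations, steps = "ingest")
  tab <- tibble::tibble(
    subject_id = vapply(observations, `[[`, character(1), "subject_id"),
    feeding_state = vapply(observations, function(o) o$condition$feeding_state,
                           character(1)),
    ingested = occ[, 1])
  dplyr::summarise(dplyr::group_by(tab, .data$subject_id, .data$feeding_state),
                   offered = dplyr::n(),
                   consumed = sum(.data$ingested),
                   .groups = "drop")
}

#' @rdname consumption_counts
#' @param counts Output of `consumption_counts()`.
#' @return `consumption_summary()` returns mean, SEM and subject count per
#'   feeding state.
#' @export
consumption_summary <- function(counts) {
  dplyr::summarise(dplyr::group_by(counts, .data$feeding_state),
                   n_subjects = dplyr::n(),
                   mean_consumed = mean(.data$consumed),
                   sem_consumed = stats::sd(.data$consumed) /
                     sqrt(dplyr::n()),
                   .groups = "drop")
}
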