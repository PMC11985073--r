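#' The canonical feeding-step alphabet
#'
#' Feeding in *Cladonema* proceeds as a stereotyped sequence of five steps:
#' prey contact with an outstretched tentacle, prey paralysis, the tentacle
#' contraction reflex (TCR), tentacle bending, and ingestion by the
#' manubrium. Steps are ranked 0 (contact) through 4 (ingest); the sequence
#' grammar requires that a step of rank r can only occur if every step of
#' lower rank occurred first.
#'
#' @return Character vector of the five step names in canonical order.
#' @examples
#' feeding_steps()
#' @export
feeding_steps <- function() {
  c("contact", "paralyze", "tcr", "bend", "ingest")
}

#' @rdname feeding_steps
#' @return `timed_steps()` returns the four steps with a timing record
#'   (everything except contact, which defines t = 0).
#' @export
timed_steps <- function() {
  feeding_steps()[-1]
}

#' Rank of a feeding step in the canonical sequence
#'
#' @param step Character vector of step names.
#' @return Integer ranks (contact = 0, ..., ingest = 4).
#' @examples
#' step_rank(c("contact", "tcr"))
#' @export
step_rank <- function(step) {
  r <- match(step, feeding_steps())
  if (anyNA(r)) {
    stop("Unknown feeding step(s): ",
         paste(unique(step[is.na(r)]), collapse = ", "),
         ". Canonical steps are: ", paste(feeding_steps(), collapse = ", "))
  }
  r - 1L
}

# internal: steps strictly later in rank than `step`
steps_after <- function(step) {
  all <- feeding_steps()
  all[step_rank(all) > step_rank(step)]
}

# internal: the canonical next step (rank + 1), or NA for ingest
next_step <- function(step) {
  all <- feeding_steps()
  r <- step_rank(step)
  if (r >= 4L) return(NA_character_)
  all[r + 2L]
}
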