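# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and survival/fisher.test etc.) so that agreement between
# the two routes is informative.

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins, probability-mass rule
fisher_enum_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  N <- sum(m)
  k <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(k, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (no ties assumed); doubled smaller tail
# capped at 1
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# hand product-limit estimator (events processed before censorings at tied
# times), returning the cumulative fraction at each event time
km_hand <- function(times, observed) {
  ord <- order(times)
  t <- times[ord]
  d <- observed[ord]
  ut <- sort(unique(t[d]))
  S <- 1
  out_t <- numeric(0)
  out_f <- numeric(0)
  for (tt in ut) {
    at_risk <- sum(t >= tt)
    dd <- sum(t == tt & d)
    S <- S * (1 - dd / at_risk)
    out_t <- c(out_t, tt)
    out_f <- c(out_f, 1 - S)
  }
  list(time = out_t, cum_fraction = out_f)
}

# hand two-group log-rank chi-square by observed-vs-expected tabulation
# over the pooled event times
logrank_hand <- function(t1, d1, t2, d2) {
  times <- sort(unique(c(t1[d1], t2[d2])))
  O <- E <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt)
    n2 <- sum(t2 >= tt)
    n <- n1 + n2
    dd1 <- sum(t1 == tt & d1)
    dd <- dd1 + sum(t2 == tt & d2)
    O <- O + dd1
    E <- E + dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (n2 / n) * (n - dd) / (n - 1)
  }
  (O - E)^2 / V
}

# build an observation from per-step (onset, offset) pairs
obs_from_times <- function(id = "obs1", paralyze = NULL, tcr = NULL,
                           bend = NULL, ingest = NULL,
                           cond = condition_label(), window = 120,
                           subject = "subj1") {
  steps <- list(paralyze = paralyze, tcr = tcr, bend = bend,
                ingest = ingest)
  steps <- steps[!vapply(steps, is.null, logical(1))]
  ev <- data.frame(step = c("contact", names(steps)),
                   onset_s = c(0, vapply(steps, `[`, numeric(1), 1)),
                   offset_s = c(0, vapply(steps, `[`, numeric(1), 2)))
  observation(id, subject, cond, ev, window_s = window)
}

# one row of the long event-table dialect
evt_row <- function(id, step, onset, offset = NA_real_, subject = id,
                    state = "starved", prep = "intact", use = "na",
                    mins = NA_integer_) {
  tibble::tibble(observation_id = id, subject_id = subject,
                 feeding_state = state, preparation = prep,
                 tentacle_use = use, minutes_since_meal = mins,
                 step = step, onset_s = onset, offset_s = offset)
}

# a degenerate config whose sequence is fully deterministic
deterministic_config <- function(pi = c(paralyze = 1, tcr = 1, bend = 1,
                                        ingest = 1)) {
  sim_config(pi = pi,
             latency_median = c(paralyze = 2, tcr = 3, bend = 4, ingest = 5),
             latency_sdlog = c(paralyze = 0, tcr = 0, bend = 0, ingest = 0),
             duration_median = c(tcr = 6, bend = 7, ingest = 8),
             duration_sdlog = c(tcr = 0, bend = 0, ingest = 0),
             preset_name = "det")
}
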