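sample_of <- function(times, observed = rep(TRUE, length(times)),
                      step = "tcr") {
  structure(list(step = step, quantity = "latency",
                 times_s = as.numeric(times), observed = observed,
                 n = length(times)),
            class = "latency_sample")
}

test_that("the KM curve reduces to the empirical CDF without censoring", {
  k <- km_curve(sample_of(c(1, 2, 3)))
  expect_equal(k$cum_fraction, c(1, 2, 3) / 3)
  expect_equal(k$percentiles[["50"]], 2)
  # randomized check at larger n against quantile-free ECDF percentiles
  set.seed(42)
  for (i in 1:20) {
    x <- round(rlnorm(sample(5:60, 1), log(5), 0.7), 3)
    k <- km_curve(sample_of(x))
    ec <- ecdf(x)
    expect_equal(k$cum_fraction, ec(k$time))
    for (q in c(25, 50, 75)) {
      expect_equal(k$percentiles[[as.character(q)]],
                   min(sort(x)[ec(sort(x)) >= q / 100]))
    }
  }
})

test_that("the product-limit estimator handles censoring as the hand computation", {
  k <- km_curve(sample_of(c(1, 2, 3), observed = c(TRUE, FALSE, TRUE)))
  # S(1) = 2/3; the censored 2 leaves one at risk at t=3, so S(3) = 0
  expect_equal(k$time, c(1, 3))
  expect_equal(k$cum_fraction, c(1 / 3, 1))
  expect_equal(k$percentiles[["50"]], 3)
  # property: matches the independent hand product-limit on random samples
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    tm <- pmin(rlnorm(n, log(8), 0.8), 120)
    obs <- tm < 120 & runif(n) > 0.2
    tm[!obs] <- pmin(tm[!obs] + rexp(sum(!obs)), 120)
    k <- km_curve(sample_of(tm, obs))
    h <- km_hand(tm, obs)
    expect_equal(k$time, h$time)
    expect_equal(k$cum_fraction, h$cum_fraction)
  }
})

test_that("an all-censored sample yields a flat curve with no percentiles", {
  expect_warning(k <- km_curve(sample_of(rep(120, 6), rep(FALSE, 6))),
                 "censored")
  expect_length(k$time, 0)
  expect_true(all(is.na(k$percentiles)))
})

test_that("enlarging the window never lowers the cumulative fraction", {
  set.seed(13)
  cfg <- preset_library()$fed
  d <- simulate_dataset(cfg, n_subjects = 30, seed = 21)
  tim120 <- extract_timings_all(d$observations)
  # re-censor the same observations at a tighter 60 s horizon
  shrink <- function(t, w) {
    t$censored <- t$censored | t$latency_s > w
    t$latency_s <- pmin(t$latency_s, w)
    t$duration_s[t$censored] <- NA_real_
    t
  }
  tim60 <- shrink(tim120, 60)
  for (st in c("paralyze", "tcr")) {
    k120 <- km_curve(latency_sample(tim120, st))
    k60 <- km_curve(latency_sample(tim60, st))
    grid <- seq(0, 59.9, by = 0.5)
    frac_at <- function(k, tt) {
      vapply(tt, function(x) {
        i <- which(k$time <= x)
        if (length(i) == 0) 0 else k$cum_fraction[max(i)]
      }, numeric(1))
    }
    expect_true(all(frac_at(k120, grid) >= frac_at(k60, grid) - 1e-12))
  }
})

test_that("log-rank is zero for identical groups and matches the hand tabulation", {
  s <- sample_of(c(2, 5, 9, 120), observed = c(TRUE, TRUE, TRUE, FALSE))
  r <- logrank_test(s, s)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_equal(r$p_two_sided, 1)

  # 4-event worked instance: A events at 1, 2; B events at 3, 4
  a <- sample_of(c(1, 2))
  b <- sample_of(c(3, 4))
  r <- logrank_test(a, b)
  expect_equal(r$chi_square, logrank_hand(c(1, 2), c(TRUE, TRUE),
                                          c(3, 4), c(TRUE, TRUE)),
               tolerance = 1e-10)
  expect_equal(r$df, 1)
  # symmetric in group order
  expect_equal(logrank_test(b, a)$chi_square, r$chi_square)
  # invariant under a joint strictly monotone time relabeling
  sq <- function(s) sample_of(s$times_s^2, s$observed)
  expect_equal(logrank_test(sq(a), sq(b))$chi_square, r$chi_square)

  # randomized agreement with the hand tabulation, with censoring
  set.seed(31)
  for (i in 1:10) {
    ta <- round(rlnorm(25, log(5), 0.6), 2)
    tb <- round(rlnorm(30, log(9), 0.6), 2)
    da <- ta < 15
    db <- tb < 15
    ta <- pmin(ta, 15)
    tb <- pmin(tb, 15)
    r <- logrank_test(sample_of(ta, da), sample_of(tb, db))
    expect_equal(r$chi_square, logrank_hand(ta, da, tb, db),
                 tolerance = 1e-8)
  }
})

test_that("T50 fold change is a ratio of KM medians, undefined when not reached", {
  fed <- sample_of(rep(10, 11))
  starved <- sample_of(rep(2, 11))
  expect_equal(t50_fold_change(fed, starved)$ratio, 5.0)
  expect_equal(t50_fold_change(starved, starved)$ratio, 1.0)
  nr <- sample_of(rep(120, 8), rep(FALSE, 8))
  u <- t50_fold_change(nr, starved)
  expect_true(is.na(u$ratio))
  expect_match(u$reason, "not reached")
  expect_false(is.infinite(u$ratio))
})

test_that("adjacent-step timing correlation recovers monotone and independent structure", {
  mk_tim <- function(tcr_lat, bend_lat) {
    dplyr::bind_rows(lapply(seq_along(tcr_lat), function(i) {
      extract_timings(obs_from_times(
        id = paste0("o", i), paralyze = c(1, 1),
        tcr = c(1 + tcr_lat[i], 2 + tcr_lat[i]),
        bend = c(2 + tcr_lat[i] + bend_lat[i],
                 3 + tcr_lat[i] + bend_lat[i])))
    }))
  }
  x <- c(1, 3, 7, 12, 20)
  r <- adjacent_timing_correlation(mk_tim(x, 2 * x + 1), "tcr", "bend")
  expect_equal(r$rho, 1.0)
  r2 <- adjacent_timing_correlation(mk_tim(x, 50 - 2 * x), "tcr", "bend")
  expect_equal(r2$rho, -1.0)
  expect_error(adjacent_timing_correlation(mk_tim(x[1:2], x[1:2]),
                                           "tcr", "bend"),
               "Fewer than 3")
  # generator draws latencies independently across steps
  d <- simulate_dataset("starved", n_subjects = 40, seed = 17)
  tim <- extract_timings_all(d$observations)
  r3 <- adjacent_timing_correlation(tim, "tcr", "bend")
  expect_lt(abs(r3$rho), 0.25)
})

test_that("KM T50 converges to the latency-distribution median with n", {
  cfg <- sim_config(pi = c(paralyze = 1, tcr = 1, bend = 1, ingest = 1),
                    latency_median = c(paralyze = 5, tcr = 6, bend = 3,
                                       ingest = 6),
                    offers_per_subject = 1, preset_name = "conv")
  err <- vapply(c(50, 500, 5000), function(n) {
    d <- simulate_dataset(cfg, n_subjects = n, seed = 1234)
    t50 <- km_curve(latency_sample(extract_timings_all(d$observations),
                                   "paralyze"))$percentiles[["50"]]
    abs(log(t50 / 5))
  }, numeric(1))
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1] + 0.02)
})
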