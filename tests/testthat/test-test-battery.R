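test_that("Fisher's exact two-sided p follows the probability-mass rule", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3)))$p_two_sided,
               34 / 70, tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p_two_sided,
               2 / 252, tolerance = 1e-10)
  # identical rows: the observed table has maximal probability
  expect_equal(fisher_exact_2x2(rbind(c(4, 6), c(4, 6)))$p_two_sided, 1)
  expect_error(fisher_exact_2x2(matrix(1, 2, 3)), "chi_square_test")
  # random tables against the enumeration oracle
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6), 2, 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m)$p_two_sided, fisher_enum_p(m),
                 tolerance = 1e-9)
  }
})

test_that("chi-square statistic, df and tail p follow the Pearson formula", {
  m <- rbind(c(10, 20), c(20, 10))
  r <- chi_square_test(m)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(r$p, pchisq(20 / 3, 1, lower.tail = FALSE))
  # a table equal to its expected table fits perfectly
  r0 <- chi_square_test(rbind(c(10, 20), c(10, 20)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "margin")
  expect_warning(chi_square_test(rbind(c(1, 9), c(2, 8))), "below 5")
  # qualitative agreement with Fisher at large n
  big <- rbind(c(60, 40), c(30, 70))
  expect_lt(abs(log10(chi_square_test(big)$p) -
                  log10(fisher_exact_2x2(big)$p_two_sided)), 1)
})

test_that("Mann-Whitney is exact for small untied samples, approximate otherwise", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_two_sided, 2 / 6, tolerance = 1e-10)
  expect_equal(r$method, "exact")
  # identical samples carry no rank information
  x <- c(1.2, 5.3, 2.2, 8.1)
  expect_equal(mann_whitney(x, x)$p_two_sided, 1, tolerance = 1e-10)
  expect_error(mann_whitney(c(1, 2), c(3, 120), censored_b = c(FALSE, TRUE)),
               "uncensored")
  # enumeration oracle over random small untied cases
  set.seed(9)
  for (i in 1:15) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- sample(seq(0.1, 50, by = 0.1), n1)
    y <- sample(setdiff(seq(0.1, 50, by = 0.1), x), n2)
    expect_equal(mann_whitney(x, y)$p_two_sided, mw_enum_p(x, y),
                 tolerance = 1e-9)
  }
  # ties force the corrected normal approximation
  expect_equal(mann_whitney(c(1, 2, 2), c(2, 3, 4))$method,
               "normal approximation")
})

test_that("Kruskal-Wallis H matches the hand-rank computation and Dunn separates groups", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  r <- kruskal_wallis_dunn(g)
  # ranks 1..6, mean ranks 1.5/3.5/5.5: H = 12/(6*7)*sum(n R^2) - 3*7
  expect_equal(unname(r$H), 12 / 42 * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 21,
               tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(nrow(r$pairwise), 3)
  expect_equal(r$m, 3)
  # all-identical groups carry no rank separation
  same <- list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2))
  r0 <- suppressWarnings(kruskal_wallis_dunn(same))
  expect_true(is.na(r0$H) || r0$H == 0)
  expect_error(kruskal_wallis_dunn(list(a = 1:3, b = numeric(0), c = 1:3)),
               "Empty")
  expect_error(kruskal_wallis_dunn(list(a = 1:3, b = 1:3)), "k >= 3")
  # versus-control pairing reports k - 1 comparisons against the first group
  rc <- kruskal_wallis_dunn(list(ctl = rnorm(10), t1 = rnorm(10),
                                 t2 = rnorm(10)), pairs = "control")
  expect_equal(rc$m, 2)
  expect_true(all(rc$pairwise$group1 == "ctl"))
  # a well-separated group drives a small adjusted p
  sep <- kruskal_wallis_dunn(list(a = 1:10, b = 1:10 + 0.5, c = 101:110))
  expect_lt(sep$pairwise$p_adj[sep$pairwise$group1 == "a" &
                                 sep$pairwise$group2 == "c"], 0.01)
})

test_that("Bonferroni adjustment scales by the family size and clips at 1", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_error(bonferroni(0.5, m = 0), "at least 1")
  expect_error(bonferroni(c(0.1, 0.2, 0.3), m = 2), "smaller")
})

test_that("all battery p-values live in [0,1] and survive group relabeling", {
  set.seed(77)
  x <- rlnorm(20, 1, 0.5)
  y <- rlnorm(25, 1.4, 0.5)
  z <- rlnorm(15, 1.2, 0.5)
  ps <- c(fisher_exact_2x2(rbind(c(7, 3), c(2, 9)))$p_two_sided,
          chi_square_test(rbind(c(7, 13), c(12, 8)))$p,
          mann_whitney(x, y)$p_two_sided,
          kruskal_wallis_dunn(list(x = x, y = y, z = z))$p_overall)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_equal(mann_whitney(y, x)$p_two_sided, mann_whitney(x, y)$p_two_sided)
  r1 <- kruskal_wallis_dunn(list(x = x, y = y, z = z))
  r2 <- kruskal_wallis_dunn(list(z = z, y = y, x = x))
  expect_equal(r1$H, r2$H)
  expect_equal(sort(r1$pairwise$p_raw), sort(r2$pairwise$p_raw))
})
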