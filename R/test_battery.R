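#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities, with margins fixed, of every table as or
#' less probable than the observed one. (An alternative two-sided rule —
#' doubling the one-sided tail — exists; the probability-mass rule is the
#' one used here and by `stats::fisher.test`, which backs this wrapper.)
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return List with `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) {
    stop("fisher_exact_2x2 requires a 2x2 table; ",
         "use chi_square_test for larger tables")
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("Counts must be non-negative integers")
  }
  list(p_two_sided = stats::fisher.test(m)$p.value)
}

#' Pearson chi-square test on an r x c table
#'
#' Uncorrected Pearson statistic with (r-1)(c-1) df and upper-tail p.
#' Warns when any expected count is below 5 (the approximation degrades);
#' errors on a zero row or column margin (expected counts of 0).
#'
#' @param table r x c matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("Counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("Zero row or column margin; expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("Some expected counts are below 5; ",
            "chi-square approximation may be poor")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact permutation p-value when the smaller sample has at most 8 values
#' and there are no ties (enumeration is cheap there); otherwise the normal
#' approximation with tie correction and continuity correction. Intended
#' for uncensored values only: passing censoring flags with any `TRUE` is
#' an error, since censored times are not exchangeable ranks.
#'
#' @param values_a,values_b Numeric samples.
#' @param censored_a,censored_b Optional logical flags asserting which
#'   values are censored; any censored value aborts.
#' @return List with `U` (for the first sample), `p_two_sided`, `method`.
#' @export
mann_whitney <- function(values_a, values_b,
                         censored_a = NULL, censored_b = NULL) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("Both samples must be non-empty")
  }
  if (any(c(censored_a, censored_b))) {
    stop("mann_whitney requires uncensored values; ",
         "use logrank_test for censored latency samples")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && min(length(values_a), length(values_b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_two_sided = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p on k - 1 df, then
#' Dunn's z statistics on mean ranks for the requested pairs with
#' Bonferroni adjustment over the number of pairs tested.
#'
#' @param groups List of k >= 3 non-empty numeric samples (names used as
#'   group labels; the first group is the control for `pairs = "control"`).
#' @param pairs `"all"` (all k(k-1)/2 pairs) or `"control"` (each group vs
#'   the first).
#' @return List with `H`, `df`, `p_overall`, and `pairwise`: a tibble of
#'   group pairs with Dunn `z`, raw and Bonferroni-adjusted p, and the
#'   family size `m` used.
#' @export
kruskal_wallis_dunn <- function(groups, pairs = c("all", "control")) {
  pairs <- match.arg(pairs)
  if (length(groups) < 3) stop("Need k >= 3 groups")
  if (any(lengths(groups) == 0)) stop("Empty group supplied")
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  kt <- stats::kruskal.test(groups)

  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  ns <- lengths(groups)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  idx <- if (pairs == "all") {
    utils::combn(seq_along(groups), 2)
  } else {
    rbind(1L, seq_along(groups)[-1])
  }
  m <- ncol(idx)
  pw <- lapply(seq_len(m), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    z <- (rbar[[i1]] - rbar[[i2]]) /
      sqrt(sigma2 * (1 / ns[[i1]] + 1 / ns[[i2]]))
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
                   z = z, p_raw = p_raw)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- bonferroni(pw$p_raw, m = m)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_overall = kt$p.value, pairwise = pw, m = m)
}

#' Bonferroni correction with an explicit family size
#'
#' Each adjusted p is `min(1, p * m)`. Unlike `stats::p.adjust`, the family
#' size `m` may exceed the number of p-values supplied (tests belonging to
#' the family but not passed in still count toward it).
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size, at least the number of p-values supplied.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("Family size m must be at least 1")
  if (m < length(p_values)) {
    stop("Family size m (", m, ") is smaller than the number of p-values (",
         length(p_values), ")")
  }
  pmin(1, p_values * m)
}
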