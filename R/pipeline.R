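#' Configuration for a full analysis run
#'
#' @param input Path to an event-table CSV, or `NULL` to simulate.
#' @param presets Character vector of preset names to simulate when `input`
#'   is `NULL` (each preset becomes one condition arm).
#' @param n_subjects Optional named integer vector overriding preset
#'   subject counts.
#' @param group_by Condition field used to split observations into arms
#'   when reading from a CSV (default `"feeding_state"`).
#' @param window_s Censoring horizon, seconds.
#' @param gray_threshold Transition probabilities strictly below this value
#'   are flagged for de-emphasized (gray) rendering; display only, never a
#'   data filter.
#' @param bonferroni_family Optional family size for between-condition
#'   tests (default: the number of tests actually run per family).
#' @param out_dir Output directory for tables, test results and figures.
#' @param seed Seed for simulation-driven runs.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, presets = c("starved", "fed"),
                            n_subjects = NULL, group_by = "feeding_state",
                            window_s = 120, gray_threshold = 0.05,
                            bonferroni_family = NULL,
                            out_dir = tempfile("jellyfeed_run_"), seed = 1) {
  if (!group_by %in% condition_fields()) {
    stop("group_by must be one of: ", paste(condition_fields(), collapse = ", "))
  }
  if (gray_threshold < 0 || gray_threshold > 1) {
    stop("gray_threshold must lie in [0, 1]")
  }
  structure(list(input = input, presets = presets, n_subjects = n_subjects,
                 group_by = group_by, window_s = window_s,
                 gray_threshold = gray_threshold,
                 bonferroni_family = bonferroni_family,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

# split observations into named condition arms
split_arms <- function(observations, group_by) {
  key <- vapply(observations, function(o) {
    v <- o$condition[[group_by]]
    if (is.na(v)) "na" else as.character(v)
  }, character(1))
  split(observations, key)
}

#' Run the full feeding-sequence analysis
#'
#' Executes parse/simulate -> timing extraction -> transition, agreement
#' and consumption statistics -> Kaplan-Meier curves, percentile times and
#' fold changes -> between-condition tests (Fisher on the collapsed 2x2
#' dominant transition, log-rank on latencies, Mann-Whitney on uncensored
#' values for two arms; chi-square and Kruskal-Wallis/Dunn for k arms),
#' and writes tidy CSV/JSON outputs plus figures and a run log under
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param render Write figure files (default `TRUE`).
#' @return The report bundle (list), invisibly: per-arm statistics, test
#'   results, and output paths.
#' @export
run_pipeline <- function(config, render = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- load or simulate ----
  truth <- NULL
  if (!is.null(config$input)) {
    parsed <- read_event_table(config$input, window_s = config$window_s)
    observations <- parsed$observations
    report <- parsed$report
  } else {
    sims <- lapply(config$presets, function(p) {
      n <- if (!is.null(config$n_subjects) && p %in% names(config$n_subjects)) {
        config$n_subjects[[p]]
      } else NULL
      simulate_dataset(p, n_subjects = n, seed = config$seed)
    })
    observations <- unlist(lapply(sims, `[[`, "observations"),
                           recursive = FALSE)
    truth <- lapply(sims, `[[`, "truth")
    names(truth) <- config$presets
    report <- list(n_accepted = length(observations),
                   n_rejected_rows = 0L, n_rejected_observations = 0L)
  }
  if (length(observations) == 0) stop("run_pipeline: no observations")

  arms <- if (is.null(config$input)) {
    # one arm per preset, in the order requested
    key <- vapply(observations, function(o) {
      sub("_s[0-9]+$", "", o$subject_id)
    }, character(1))
    split(observations, factor(key, levels = config$presets))
  } else {
    split_arms(observations, config$group_by)
  }
  arms <- arms[lengths(arms) > 0]
  if (length(arms) == 0) stop("run_pipeline: no observations in any arm")

  # ---- per-arm statistics ----
  from_steps <- feeding_steps()[-5]
  per_arm <- lapply(arms, function(obs) {
    timings <- extract_timings_all(obs)
    transitions <- lapply(from_steps, function(fs) {
      tryCatch(transition_matrix(obs, fs), error = function(e) NULL)
    })
    names(transitions) <- from_steps
    agreement <- lapply(c("paralyze", "tcr", "bend"), function(st) {
      agreement_probability(obs, st)
    })
    names(agreement) <- c("paralyze", "tcr", "bend")
    samples <- lapply(timed_steps(), function(st) {
      latency_sample(timings, st)
    })
    names(samples) <- timed_steps()
    curves <- lapply(samples, function(s) suppressWarnings(km_curve(s)))
    list(n = length(obs), timings = timings, transitions = transitions,
         agreement = agreement, samples = samples, curves = curves,
         consumption = consumption_counts(obs))
  })

  # ---- between-arm tests ----
  tests <- list()
  arm_names <- names(arms)
  k <- length(arms)
  fam <- config$bonferroni_family
  if (k == 2) {
    a <- per_arm[[1]]; b <- per_arm[[2]]
    trans_tests <- lapply(from_steps, function(fs) {
      ta <- a$transitions[[fs]]; tb <- b$transitions[[fs]]
      if (is.null(ta) || is.null(tb)) return(NULL)
      tab <- transition_2x2(ta, tb, labels = arm_names)
      list(from_step = fs, table = tab,
           p = fisher_exact_2x2(tab)$p_two_sided)
    })
    trans_tests <- Filter(Negate(is.null), trans_tests)
    m <- if (is.null(fam)) length(trans_tests) else fam
    tests$transitions <- lapply(trans_tests, function(tt) {
      tt$p_adj <- bonferroni(tt$p, m); tt
    })
    lr <- lapply(timed_steps(), function(st) {
      r <- suppressWarnings(logrank_test(a$samples[[st]], b$samples[[st]]))
      r$step <- st
      r
    })
    m_lr <- if (is.null(fam)) length(lr) else fam
    tests$logrank <- lapply(lr, function(r) {
      r$p_adj <- bonferroni(r$p_two_sided, m_lr); r
    })
    tests$mann_whitney <- lapply(timed_steps(), function(st) {
      va <- a$samples[[st]]; vb <- b$samples[[st]]
      xa <- va$times_s[va$observed]; xb <- vb$times_s[vb$observed]
      if (length(xa) == 0 || length(xb) == 0) return(NULL)
      r <- mann_whitney(xa, xb)
      r$step <- st
      r
    })
    tests$t50_fold <- lapply(timed_steps(), function(st) {
      r <- t50_fold_change(b$samples[[st]], a$samples[[st]])
      r$step <- st
      r$direction <- paste(arm_names[2], "over", arm_names[1])
      r
    })
  } else if (k >= 3) {
    tests$chi_square <- lapply(from_steps, function(fs) {
      tabs <- lapply(per_arm, function(x) x$transitions[[fs]])
      if (any(vapply(tabs, is.null, logical(1)))) return(NULL)
      nxt <- next_step(fs)
      m2 <- t(vapply(tabs, function(tt) {
        kk <- tt$counts[match(nxt, tt$outcomes)]
        c(kk, tt$n - kk)
      }, numeric(2)))
      dimnames(m2) <- list(arm_names, c(nxt, "other"))
      r <- tryCatch(suppressWarnings(chi_square_test(m2)),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      r$from_step <- fs
      r$expected <- NULL
      r
    })
    tests$logrank <- lapply(timed_steps(), function(st) {
      samples <- lapply(per_arm, function(x) x$samples[[st]])
      if (any(vapply(samples, function(s) s$n, integer(1)) == 0)) return(NULL)
      r <- suppressWarnings(logrank_test(samples))
      r$step <- st
      r
    })
    tests$kruskal_dunn <- lapply(timed_steps(), function(st) {
      groups <- lapply(per_arm, function(x) {
        s <- x$samples[[st]]
        s$times_s[s$observed]
      })
      if (any(lengths(groups) == 0)) return(NULL)
      r <- kruskal_wallis_dunn(groups, pairs = "control")
      r$step <- st
      r
    })
  }

  # ---- outputs ----
  paths <- list()
  trans_tab <- dplyr::bind_rows(lapply(arm_names, function(an) {
    tabs <- Filter(Negate(is.null), per_arm[[an]]$transitions)
    tidy <- transition_tidy(stats::setNames(tabs, rep(an, length(tabs))))
    tidy$gray <- tidy$probability < config$gray_threshold
    tidy
  }))
  paths$transitions <- file.path(config$out_dir, "transitions.csv")
  readr::write_csv(trans_tab, paths$transitions)

  km_tab <- dplyr::bind_rows(lapply(timed_steps(), function(st) {
    km_tidy(lapply(per_arm, function(x) x$curves[[st]]), step = st)
  }))
  paths$km <- file.path(config$out_dir, "km_curves.csv")
  readr::write_csv(km_tab, paths$km)

  pct_tab <- dplyr::bind_rows(lapply(arm_names, function(an) {
    dplyr::bind_rows(lapply(timed_steps(), function(st) {
      p <- per_arm[[an]]$curves[[st]]$percentiles
      tibble::tibble(condition = an, step = st,
                     t25 = p[["25"]], t50 = p[["50"]], t75 = p[["75"]],
                     n = per_arm[[an]]$curves[[st]]$n)
    }))
  }))
  paths$percentiles <- file.path(config$out_dir, "percentiles.csv")
  readr::write_csv(pct_tab, paths$percentiles)

  results_json <- list(
    tests = tests,
    agreement = lapply(per_arm, function(x) {
      lapply(x$agreement, function(a) {
        list(step = a$step, n = a$n, n_concordant = a$n_concordant,
             probability = a$probability)
      })
    }),
    consumption = lapply(per_arm, function(x) {
      s <- consumption_summary(x$consumption)
      lapply(split(s, seq_len(nrow(s))), as.list)
    }))
  paths$results <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(results_json, paths$results, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  log <- list(seed = config$seed,
              window_s = config$window_s,
              arms = stats::setNames(lapply(per_arm, `[[`, "n"), arm_names),
              parse_report = report[c("n_accepted", "n_rejected_rows",
                                      "n_rejected_observations")],
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              package_version = as.character(utils::packageVersion("jellyfeed")))
  paths$log <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

  if (render) {
    heat_tabs <- lapply(arm_names, function(an) {
      Filter(Negate(is.null), per_arm[[an]]$transitions)
    })
    names(heat_tabs) <- arm_names
    paths$heatmap <- file.path(config$out_dir, "transition_heatmaps.pdf")
    render_heatmap(heat_tabs, gray_threshold = config$gray_threshold,
                   file = paths$heatmap)
    paths$km_figure <- file.path(config$out_dir, "km_and_boxes.pdf")
    render_km_and_boxes(per_arm, file = paths$km_figure)
  }

  bundle <- list(per_arm = per_arm, tests = tests, truth = truth,
                 paths = paths, log = log, config = config)
  invisible(bundle)
}

#' Render transition-probability heatmaps
#'
#' One panel per condition and from-step, annotated with probabilities and
#' per-panel n; cells strictly below the gray threshold are de-emphasized
#' (a display convention only — the underlying tables always keep every
#' transition).
#'
#' @param tables Named list (by condition) of lists of `transition_table`s.
#' @param gray_threshold Strict lower display threshold.
#' @param file Optional output file (PDF device; use `NULL` to get the
#'   ggplot object).
#' @return The ggplot object, invisibly when written to file.
#' @export
render_heatmap <- function(tables, gray_threshold = 0.05, file = NULL) {
  if (length(tables) == 0) stop("No transition tables to render")
  dat <- dplyr::bind_rows(lapply(names(tables), function(cond) {
    tidy <- transition_tidy(
      stats::setNames(tables[[cond]], rep(cond, length(tables[[cond]]))))
    tidy
  }))
  dat$gray <- dat$probability < gray_threshold
  dat$panel <- sprintf("%s: from %s (n = %d)", dat$condition, dat$from_step,
                       dat$n)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$outcome, y = "P")) +
    ggplot2::geom_tile(ggplot2::aes(fill = ifelse(.data$gray, NA_real_,
                                                  .data$probability)),
                       color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability),
                                    color = .data$gray), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85",
                                 name = "P") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black",
                                           `TRUE` = "grey55"),
                                guide = "none") +
    ggplot2::facet_wrap(~panel, ncol = 4, scales = "free_x") +
    ggplot2::labs(x = "outcome", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 10, height = 2 + 1.5 * length(tables))
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}

#' Render Kaplan-Meier curves with percentile boxes
#'
#' Step-function cumulative-fraction curves per feeding step (solid for the
#' first condition, dashed for later ones) with companion boxes spanning
#' T25-T75, a bar at T50, whiskers at the minimum/maximum uncensored
#' times, and the T50 fold change annotated for two-arm runs. Percentiles
#' never reached are omitted with an annotation.
#'
#' @param per_arm Named per-arm statistics list as built by
#'   [run_pipeline()] (each with `samples` and `curves`).
#' @param file Optional output PDF path.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_km_and_boxes <- function(per_arm, file = NULL) {
  arm_names <- names(per_arm)
  km_dat <- dplyr::bind_rows(lapply(timed_steps(), function(st) {
    dplyr::bind_rows(lapply(arm_names, function(an) {
      k <- per_arm[[an]]$curves[[st]]
      if (length(k$time) == 0) {
        return(tibble::tibble(condition = an, step = st, time = c(0, 120),
                              cum_fraction = c(0, 0)))
      }
      tibble::tibble(condition = an, step = st,
                     time = c(0, k$time), cum_fraction = c(0, k$cum_fraction))
    }))
  }))
  km_dat$step <- factor(km_dat$step, levels = timed_steps())
  fold_lab <- if (length(arm_names) == 2) {
    dplyr::bind_rows(lapply(timed_steps(), function(st) {
      f <- t50_fold_change(per_arm[[2]]$samples[[st]],
                           per_arm[[1]]$samples[[st]])
      tibble::tibble(step = factor(st, levels = timed_steps()),
                     label = if (is.na(f$ratio)) "T50 not reached"
                             else sprintf("T50 fold %.1f", f$ratio))
    }))
  } else NULL
  p <- ggplot2::ggplot(km_dat,
                       ggplot2::aes(x = .data$time, y = .data$cum_fraction,
                                    linetype = .data$condition,
                                    color = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~step, ncol = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "cumulative fraction") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(fold_lab)) {
    p <- p + ggplot2::geom_text(
      data = fold_lab,
      ggplot2::aes(x = Inf, y = 0.08, label = .data$label),
      hjust = 1.05, size = 3, inherit.aes = FALSE)
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 6)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
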