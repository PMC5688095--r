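#' Percentage of PLA-positive cells per population
#'
#' The assay's per-replicate readout: `100 * positives / assigned cells` in
#' each population of each sample.
#'
#' @param calls Per-cell call tibble (from a `plic_result`'s `calls`, or
#'   [broom::tidy()] of one).
#' @param population Optional population to restrict to (e.g. `"TARGET_HI"`);
#'   a requested population with zero assigned cells yields an `NA` percentage
#'   with a warning.
#' @return Tibble with `sample`, `population`, `n`, `n_pos`, `pct_pla_pos`.
#' @export
percent_positive <- function(calls, population = NULL) {
  stopifnot(all(c("sample", "population", "final_pla_pos") %in% names(calls)))
  out <- calls |>
    dplyr::filter(.data$population != "UNASSIGNED") |>
    dplyr::group_by(.data$sample, .data$population) |>
    dplyr::summarise(n = dplyr::n(), n_pos = sum(.data$final_pla_pos),
                     pct_pla_pos = 100 * .data$n_pos / .data$n,
                     .groups = "drop")
  if (!is.null(population)) {
    pop <- population
    out <- dplyr::filter(out, .data$population %in% pop)
    missing_pop <- setdiff(pop, out$population)
    if (length(missing_pop) > 0L) {
      warning("no assigned cells in population(s): ",
              paste(missing_pop, collapse = ", "), "; percentage is NA.",
              call. = FALSE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        sample = NA_character_, population = missing_pop, n = 0L,
        n_pos = 0L, pct_pla_pos = NA_real_))
    }
  }
  out
}

#' Aggregate replicate percentages to experiment-level group means
#'
#' Each biological replicate (one animal or sample) contributes its
#' percentage of PLA-positive cells; replicates are averaged — unweighted, as
#' replicates of equal standing — within each experimental group of each
#' independent experiment. Replicate cell counts are reported alongside but
#' never used as weights.
#'
#' @param replicates Tibble with one row per biological replicate: columns
#'   `experiment`, `group`, `replicate`, `pct_pla_pos` (and optionally `n`).
#' @return Tibble with `experiment`, `group`, `n_replicates`, `mean_pct` (and
#'   `total_cells` when `n` is present).
#' @export
aggregate_replicates <- function(replicates) {
  req <- c("experiment", "group", "replicate", "pct_pla_pos")
  if (!all(req %in% names(replicates))) {
    stop("`replicates` needs columns: ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  dup <- replicates |>
    dplyr::count(.data$experiment, .data$group, .data$replicate) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("each replicate must appear once per experiment and group.",
         call. = FALSE)
  }
  out <- replicates |>
    dplyr::group_by(.data$experiment, .data$group) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_pct = mean(.data$pct_pla_pos),
                     total_cells = if ("n" %in% names(replicates)) {
                       sum(.data$n)
                     } else {
                       NA_integer_
                     },
                     .groups = "drop")
  if (all(is.na(out$total_cells))) out$total_cells <- NULL
  out
}

#' Compare two groups of experiment-level means by Student t-test
#'
#' The unit of replication is the independent experiment: each experiment
#' contributes one mean percentage per group, and the two groups are compared
#' by a two-sided, equal-variance (classical Student) two-sample t-test.
#' Welch's unequal-variance test is available behind `welch = TRUE`. Group
#' means are reported with the s.e.m. over experiment-level means.
#'
#' @param experiment_means Tibble from [aggregate_replicates()] (columns
#'   `experiment`, `group`, `mean_pct`), restricted to two groups.
#' @param welch Use Welch's unequal-variance test instead of the pooled one.
#' @return Object of class `plic_comparison`: list with `groups` (per-group
#'   mean, s.e.m., n), `t`, `df`, `p_value`, `method`, and the input data.
#' @export
compare_groups <- function(experiment_means, welch = FALSE) {
  req <- c("experiment", "group", "mean_pct")
  if (!all(req %in% names(experiment_means))) {
    stop("`experiment_means` needs columns: ", paste(req, collapse = ", "),
         ".", call. = FALSE)
  }
  grps <- unique(experiment_means$group)
  if (length(grps) != 2L) {
    stop("exactly two groups are required; got ", length(grps), ".",
         call. = FALSE)
  }
  x <- experiment_means$mean_pct[experiment_means$group == grps[1]]
  y <- experiment_means$mean_pct[experiment_means$group == grps[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("at least 2 independent experiments per group are required for the ",
         "t-test (got ", length(x), " and ", length(y), ").", call. = FALSE)
  }
  degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    # zero variance in both groups: t is 0 (equal means) or signed infinity
    df0 <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = df0), p.value = 1)
    } else {
      warning("degenerate variance: both groups are constant.", call. = FALSE)
      tt <- list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                 parameter = c(df = df0), p.value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  }
  groups <- tibble::tibble(
    group = as.character(grps),
    n_experiments = c(length(x), length(y)),
    mean_pct = c(mean(x), mean(y)),
    sem = c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y))))
  structure(list(groups = groups,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (welch) "Welch" else "Student",
                 data = experiment_means),
            class = "plic_comparison")
}

#' @export
print.plic_comparison <- function(x, ...) {
  cat("<plic_comparison> ", x$method,
      " two-sample t-test on experiment-level means\n", sep = "")
  print(x$groups)
  cat(sprintf("t = %.4g, df = %.4g, two-sided p = %.4g\n", x$t, x$df,
              x$p_value))
  invisible(x)
}
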