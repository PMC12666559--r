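#' Per-frame cell-cycle phase fractions across a cohort
#'
#' Computes, at every frame, the percentage of labelled cells in G1, S and
#' G2/M. Indeterminate (U) frames are excluded from the denominator by
#' default, so the three phase percentages sum to 100 wherever at least one
#' cell carries a phase label; frames with no labelled cell yield `NA`
#' percentages rather than zeros.
#'
#' @param labels Long label tibble (`cell_id`, `frame`, `time_h`, `label`)
#'   from [call_phases_cohort()] or [call_cycle_timings()].
#' @param drop_u Exclude U frames from the denominator (default `TRUE`).
#'
#' @return A tibble of class `fucci_fractions` with columns `frame`,
#'   `time_h`, `n_labeled`, `phase`, `pct` (long format, one row per frame
#'   and phase).
#' @export
phase_fraction_timecourse <- function(labels, drop_u = TRUE) {
  if (!all(c("frame", "label") %in% names(labels))) {
    stop_fucci("`labels` needs columns frame and label.", "bad-argument")
  }
  if (nrow(labels) == 0) stop_fucci("`labels` is empty.", "bad-argument")
  phases <- c("G1", "S", "G2M", if (!drop_u) "U")
  per_frame <- labels |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(time_h = .data$time_h[1],
                     n_labeled = sum(.data$label %in% phases),
                     .groups = "drop")
  counts <- labels |>
    dplyr::filter(.data$label %in% phases) |>
    dplyr::count(.data$frame, .data$label)
  out <- tidyr::expand_grid(frame = per_frame$frame, label = phases) |>
    dplyr::left_join(counts, by = c("frame", "label")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::left_join(per_frame, by = "frame") |>
    dplyr::transmute(
      frame = .data$frame, time_h = .data$time_h,
      n_labeled = .data$n_labeled,
      phase = factor(.data$label, levels = phases),
      pct = ifelse(.data$n_labeled > 0, 100 * .data$n / .data$n_labeled,
                   NA_real_)
    ) |>
    dplyr::arrange(.data$frame, .data$phase)
  class(out) <- c("fucci_fractions", class(out))
  out
}

#' Nuclear ratio (end-of-observation fold change in nucleus count)
#'
#' The proliferation proxy used for FUCCI imaging fields: nuclei at the end
#' of observation divided by nuclei at the start. A ratio near 1.0 indicates
#' potential cell-cycle arrest, above 1.0 proliferation, and below 1.0 cell
#' loss.
#'
#' @param count_start,count_end Nucleus counts (non-negative; `count_start`
#'   must be positive).
#' @return The fold change `count_end / count_start`.
#' @examples
#' nuclear_ratio(100, 140) # 1.4-fold growth
#' @export
nuclear_ratio <- function(count_start, count_end) {
  check_number(count_start, "count_start", lower = 0)
  check_number(count_end, "count_end", lower = 0)
  if (count_start == 0) {
    stop_fucci("`count_start` must be > 0.", "bad-argument")
  }
  count_end / count_start
}

#' Cohort summary of a cell-cycle transition time
#'
#' Mean, sample SD (n - 1 denominator) and SEM of one transition time over
#' the cells that completed the cycle.
#'
#' @param timings Per-cell timing tibble from [call_cycle_timings()] (or any
#'   tibble with `complete` and the `t_*` columns).
#' @param which Transition: `"g1s"`, `"sg2"` or `"mg1"`.
#' @return A one-row tibble `transition`, `n`, `mean`, `sd`, `sem` (hours).
#' @export
summarize_transitions <- function(timings, which = c("g1s", "sg2", "mg1")) {
  which <- match.arg(which)
  col <- paste0("t_", which)
  x <- timings[[col]][timings$complete]
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop_fucci("Need >= 2 complete cells to summarize a transition.",
               "too-few-cells")
  }
  tibble::tibble(transition = which, n = length(x), mean = mean(x),
                 sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)))
}

#' Phase-coupling regression of M/G1 time on G1/S time
#'
#' Ordinary least-squares fit `t_mg1 = s * t_g1s + i` over complete cells,
#' with the Pearson correlation of the pairs. The slope measures how the
#' post-restriction-point programme (S/G2/M) scales with G1/S timing: slope
#' 1 means a fixed-duration downstream programme appended to whenever the
#' cell entered S phase; slope below 1 means late-entering cells compress
#' their S/G2/M phase.
#'
#' @param timings Per-cell timing tibble (needs `t_g1s`, `t_mg1`,
#'   `complete`), or a plain tibble of pairs.
#' @return An object of class `transition_fit`: a list with `slope`,
#'   `intercept`, `r`, `n`, `data` (the pairs used) and the underlying
#'   [stats::lm] fit. [tidy()] and [glance()] methods are provided.
#' @examples
#' tt <- tibble::tibble(t_g1s = 1:10, t_mg1 = 1:10 + 17, complete = TRUE)
#' transition_regression(tt)
#' @export
transition_regression <- function(timings) {
  d <- timings
  if ("complete" %in% names(d)) d <- dplyr::filter(d, .data$complete)
  d <- dplyr::filter(d, !is.na(.data$t_g1s), !is.na(.data$t_mg1))
  if (nrow(d) < 3) {
    stop_fucci("Need >= 3 complete (t_g1s, t_mg1) pairs.", "too-few-cells")
  }
  if (stats::sd(d$t_g1s) == 0) {
    stop_fucci("`t_g1s` is constant; slope undefined.", "degenerate-input")
  }
  fit <- stats::lm(t_mg1 ~ t_g1s, data = d)
  out <- list(
    slope = unname(stats::coef(fit)[["t_g1s"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r = stats::cor(d$t_g1s, d$t_mg1),
    n = nrow(d),
    data = tibble::as_tibble(d[c("t_g1s", "t_mg1")]),
    fit = fit
  )
  class(out) <- "transition_fit"
  out
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "Transition coupling fit (n = %d cells)\n  t_mg1 = %.3f * t_g1s + %.2f h\n  Pearson r = %.3f\n",
    x$n, x$slope, x$intercept, x$r))
  invisible(x)
}

#' Early/late stratification of G1/S entry and S/G2/M duration comparison
#'
#' Splits complete cells at the median G1/S transition time (ties at the
#' median go to the early group), summarises the S/G2/M duration
#' (`dur_sgm`) in each group, and compares the groups with a two-sided
#' Welch t test. Under negative phase coupling (e.g. CDK4 inhibition),
#' late-entering cells run a shorter S/G2/M programme, so the early group's
#' mean duration exceeds the late group's.
#'
#' @param timings Per-cell timing tibble (needs `t_g1s`, `dur_sgm`,
#'   `complete`); at least 4 complete cells.
#' @return An object of class `early_late_split`: list with `median_g1s`,
#'   `groups` (per-group n/mean/sd/sem of `dur_sgm`), `p_value` (Welch),
#'   `assignments` (per-cell group tibble). [tidy()]/[glance()] methods are
#'   provided.
#' @export
early_late_split <- function(timings) {
  d <- timings
  if ("complete" %in% names(d)) d <- dplyr::filter(d, .data$complete)
  d <- dplyr::filter(d, !is.na(.data$t_g1s), !is.na(.data$dur_sgm))
  if (nrow(d) < 4) {
    stop_fucci("Need >= 4 complete cells for an early/late split.",
               "too-few-cells")
  }
  med <- stats::median(d$t_g1s)
  if (stats::sd(d$t_g1s) == 0) {
    stop_fucci("All t_g1s identical; the median split is degenerate.",
               "degenerate-input")
  }
  d$group <- ifelse(d$t_g1s <= med, "early", "late")
  if (length(unique(d$group)) < 2) {
    stop_fucci("Median split produced a single group.", "degenerate-input")
  }
  groups <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$dur_sgm),
                     sd = stats::sd(.data$dur_sgm),
                     sem = stats::sd(.data$dur_sgm) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
  p <- if (min(groups$n) >= 2) {
    stats::t.test(dur_sgm ~ group, data = d, var.equal = FALSE)$p.value
  } else {
    rlang::warn("A split group has fewer than 2 cells; Welch p is NA.")
    NA_real_
  }
  out <- list(median_g1s = med, groups = groups, p_value = p,
              assignments = tibble::as_tibble(
                d[c(intersect("cell_id", names(d)), "t_g1s", "dur_sgm", "group")]))
  class(out) <- "early_late_split"
  out
}

#' @export
print.early_late_split <- function(x, ...) {
  cat(sprintf("Early/late split at median t_g1s = %.2f h (Welch p = %.3g)\n",
              x$median_g1s, x$p_value))
  print(x$groups)
  invisible(x)
}
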