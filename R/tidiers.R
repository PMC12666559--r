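#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transition-coupling fit
#'
#' @param x A `transition_fit` from [transition_regression()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`slope`, `intercept`) and
#'   columns `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.transition_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.transition_fit
#' @return `glance()`: a one-row tibble `slope`, `intercept`, `r`,
#'   `r.squared`, `n`.
#' @export
glance.transition_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r.squared = x$r^2, n = x$n)
}

#' Tidy an early/late stratification
#'
#' @param x An `early_late_split` from [early_late_split()].
#' @param ... Unused.
#' @return Per-group S/G2/M duration summaries (`group`, `n`, `mean`, `sd`,
#'   `sem`).
#' @export
tidy.early_late_split <- function(x, ...) x$groups

#' @rdname tidy.early_late_split
#' @return `glance()`: a one-row tibble `median_g1s`, `mean_early`,
#'   `mean_late`, `gap`, `p_value`.
#' @export
glance.early_late_split <- function(x, ...) {
  g <- x$groups
  tibble::tibble(
    median_g1s = x$median_g1s,
    mean_early = g$mean[g$group == "early"],
    mean_late = g$mean[g$group == "late"],
    gap = g$mean[g$group == "early"] - g$mean[g$group == "late"],
    p_value = x$p_value
  )
}
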