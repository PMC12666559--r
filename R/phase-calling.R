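#' Call per-frame cell-cycle phases from a two-channel FUCCI trace
#'
#' Applies the dual-reporter rule table frame by frame: PIP-positive only is
#' G1 (PIP degron present, geminin absent), hGem-positive only is S (PIP
#' degraded during replication), both positive is G2/M, and both
#' sub-threshold is U (indeterminate; typically the brief mitotic gap or a
#' tracking dropout). A label median filter then removes single-frame
#' flicker.
#'
#' @param trace A data frame with one cell's trace: columns `time_h`
#'   (strictly increasing), `hgem` and `pip` (finite, >= 0), optionally
#'   `cell_id`.
#' @param thresholds A one-row data frame with `hgem_thr` and `pip_thr`
#'   (from [estimate_thresholds()]), or a named vector/list with elements
#'   `hgem_thr`/`pip_thr`.
#' @param smooth_frames Odd window width (frames) for the label median
#'   filter; 1 disables smoothing. Default 3 (one hour at 20-min frames).
#'
#' @return A tibble with columns `cell_id` (if present in the input),
#'   `frame`, `time_h` and `label` (one of `"G1"`, `"S"`, `"G2M"`, `"U"`).
#'
#' @details The rule table is exhaustive and mutually exclusive for any
#'   finite intensity pair, and is invariant to rescaling a channel together
#'   with its threshold. The median filter takes the majority label in each
#'   centred window (windows shrink at the trace ends); ties keep the
#'   previous output frame's label, so smoothing is causally stable.
#'
#' @examples
#' tr <- tibble::tibble(time_h = (0:5) / 3, hgem = c(0, 0, 2, 2, 2, 0),
#'                      pip = c(2, 2, 0, 0, 2, 2))
#' call_phases(tr, c(hgem_thr = 1, pip_thr = 1), smooth_frames = 1)
#' @export
call_phases <- function(trace, thresholds, smooth_frames = 3) {
  validate_trace(trace)
  thr <- as.list(thresholds)
  check_number(thr$hgem_thr, "hgem_thr", lower = 0)
  check_number(thr$pip_thr, "pip_thr", lower = 0)
  if (thr$hgem_thr <= 0 || thr$pip_thr <= 0) {
    stop_fucci("Thresholds must be strictly positive.", "bad-argument")
  }
  if (smooth_frames < 1 || smooth_frames %% 2 != 1) {
    stop_fucci("`smooth_frames` must be a positive odd integer.", "bad-argument")
  }
  hg <- trace$hgem > thr$hgem_thr
  pp <- trace$pip > thr$pip_thr
  label <- dplyr::case_when(
    pp & !hg ~ "G1",
    hg & !pp ~ "S",
    hg & pp ~ "G2M",
    .default = "U"
  )
  label <- median_filter_labels(label, smooth_frames)
  out <- tibble::tibble(frame = seq_along(label), time_h = trace$time_h,
                        label = label)
  if ("cell_id" %in% names(trace)) {
    out <- tibble::add_column(out, cell_id = trace$cell_id, .before = 1)
  }
  out
}

validate_trace <- function(trace) {
  need <- c("time_h", "hgem", "pip")
  if (!all(need %in% names(trace))) {
    stop_fucci("`trace` needs columns time_h, hgem, pip.", "bad-argument")
  }
  if (nrow(trace) == 0) stop_fucci("`trace` is empty.", "bad-argument")
  if (length(unique(stats::na.omit(trace[["cell_id"]]))) > 1) {
    stop_fucci("`trace` must contain a single cell; see call_phases_cohort().",
               "bad-argument")
  }
  if (anyNA(trace$time_h) || any(diff(trace$time_h) <= 0)) {
    stop_fucci("`time_h` must be strictly increasing.", "bad-argument")
  }
  check_finite_nonneg(trace$hgem, "hgem")
  check_finite_nonneg(trace$pip, "pip")
  invisible(trace)
}

# Majority label in a centred window; ties keep the previous output label
# (the raw label at the first frame).
median_filter_labels <- function(label, width) {
  if (width == 1 || length(label) == 1) return(label)
  half <- (width - 1L) %/% 2L
  n <- length(label)
  out <- label
  for (i in seq_len(n)) {
    win <- label[max(1L, i - half):min(n, i + half)]
    counts <- table(win)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1L) {
      out[i] <- top
    } else if (i > 1L && out[i - 1L] %in% top) {
      out[i] <- out[i - 1L]
    } else if (!(label[i] %in% top)) {
      out[i] <- top[1L]
    } # else keep the raw label
  }
  out
}

#' Extract cell-cycle transition times from a phase-label sequence
#'
#' Runs a forward state machine over the canonical first cycle
#' G1 -> S -> G2/M -> (U?) -> G1. A state change is accepted only when the
#' new label persists for at least `min_dwell_frames` consecutive frames, so
#' residual label flicker cannot create spurious transitions. The M/G1
#' transition is read as geminin loss after G2/M: the first accepted frame
#' where the label leaves G2M (to U or to G1).
#'
#' @param labels Character vector of per-frame labels (`"G1"`, `"S"`,
#'   `"G2M"`, `"U"`), or the tibble returned by [call_phases()].
#' @param times Numeric vector of frame times in hours (ignored when
#'   `labels` is a [call_phases()] tibble, which carries its own `time_h`).
#' @param min_dwell_frames Minimum consecutive frames a new state must
#'   persist to be accepted. Default 3 (one hour at 20-min frames).
#'
#' @return A one-row tibble: `t_g1s`, `t_sg2`, `t_mg1` (h, `NA` when the
#'   transition was not observed), `dur_g1`, `dur_s`, `dur_g2m`, `dur_sgm`
#'   (h), `complete` (all three transitions accepted within the trace), and
#'   `status` -- one of `"complete"`, `"incomplete"` (arrested or ran out of
#'   horizon), `"pre-cycling"` (trace begins in S or G2/M, so the first
#'   cycle's start was not observed), `"non-canonical"` (a dwell-accepted
#'   phase order the cycle does not allow, e.g. S -> G1).
#'
#' @details Transition times are the time stamp of the first frame in the
#'   new state, with no sub-frame interpolation. U runs before the first G1
#'   run are skipped (reporters not yet visible); U runs while in G1 or S
#'   are treated as transparent dropout rather than a phase, since the
#'   cycle places an indeterminate gap only around mitosis. `dur_g1` is
#'   measured from the first frame; `dur_sgm = t_mg1 - t_g1s`.
#'
#' @examples
#' lab <- rep(c("G1", "S", "G2M", "U"), each = 9)
#' extract_timings(lab, seq_along(lab) / 3 - 1 / 3)
#' @export
extract_timings <- function(labels, times = NULL, min_dwell_frames = 3) {
  if (is.data.frame(labels)) {
    times <- labels$time_h
    labels <- labels$label
  }
  if (length(labels) != length(times)) {
    stop_fucci("`labels` and `times` must have the same length.", "bad-argument")
  }
  if (!all(labels %in% phase_levels())) {
    stop_fucci("Labels must be G1, S, G2M or U.", "bad-argument")
  }
  check_number(min_dwell_frames, "min_dwell_frames", lower = 1)

  na_row <- function(status, t_g1s = NA_real_, t_sg2 = NA_real_,
                     t_mg1 = NA_real_) {
    tibble::tibble(
      t_g1s = t_g1s, t_sg2 = t_sg2, t_mg1 = t_mg1,
      dur_g1 = t_g1s - times[1],
      dur_s = t_sg2 - t_g1s,
      dur_g2m = t_mg1 - t_sg2,
      dur_sgm = t_mg1 - t_g1s,
      complete = status == "complete",
      status = status
    )
  }

  runs <- rle(labels)
  starts <- cumsum(c(1L, utils::head(runs$lengths, -1L)))
  first_real <- which(runs$values != "U")
  if (length(first_real) == 0) return(na_row("incomplete"))
  first_real <- first_real[1]
  if (runs$values[first_real] != "G1") return(na_row("pre-cycling"))

  state <- "G1"
  nxt <- c(G1 = "S", S = "G2M")
  t_g1s <- t_sg2 <- t_mg1 <- NA_real_
  idx <- first_real + 1L
  while (idx <= length(runs$values)) {
    lab <- runs$values[idx]
    len <- runs$lengths[idx]
    t0 <- times[starts[idx]]
    accepted <- len >= min_dwell_frames
    if (lab == state || !accepted && lab != "U") {
      # same state, or sub-dwell flicker: ignore
    } else if (lab == "U") {
      if (state == "G2M" && accepted) {
        t_mg1 <- t0
        break
      }
      # transparent dropout in G1/S (any length) or sub-dwell mitotic dip
    } else if (state %in% names(nxt) && lab == nxt[[state]]) {
      if (state == "G1") t_g1s <- t0 else t_sg2 <- t0
      state <- lab
    } else if (state == "G2M" && lab == "G1") {
      t_mg1 <- t0
      break
    } else {
      return(na_row("non-canonical", t_g1s, t_sg2))
    }
    idx <- idx + 1L
  }
  status <- if (!is.na(t_mg1)) "complete" else "incomplete"
  na_row(status, t_g1s, t_sg2, t_mg1)
}

#' Phase-call and time a whole cohort of FUCCI traces
#'
#' Convenience pipeline over a long trace table: pools intensities to
#' estimate thresholds (unless supplied), calls per-frame phases per cell,
#' and extracts per-cell transition times.
#'
#' @param traces Long tibble with columns `cell_id`, `time_h`, `hgem`, `pip`
#'   (as written by [gen_fucci_traces()] or [read_traces()]).
#' @param thresholds Optional threshold row (see [call_phases()]); estimated
#'   automatically from the pooled cohort intensities when `NULL`.
#' @inheritParams call_phases
#' @inheritParams extract_timings
#'
#' @return A tibble with one row per cell (`cell_id` plus every
#'   [extract_timings()] column). The per-frame label table is attached as
#'   attribute `"labels"`, and the thresholds used as attribute
#'   `"thresholds"`.
#' @export
call_cycle_timings <- function(traces, thresholds = NULL, smooth_frames = 3,
                               min_dwell_frames = 3) {
  if (!all(c("cell_id", "time_h", "hgem", "pip") %in% names(traces))) {
    stop_fucci("`traces` needs columns cell_id, time_h, hgem, pip.",
               "bad-argument")
  }
  if (is.null(thresholds)) {
    thresholds <- estimate_thresholds(traces$hgem, traces$pip)
  }
  labels <- call_phases_cohort(traces, thresholds, smooth_frames)
  timings <- labels |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ extract_timings(.x$label, .x$time_h,
                                          min_dwell_frames)) |>
    dplyr::ungroup()
  attr(timings, "labels") <- labels
  attr(timings, "thresholds") <- thresholds
  timings
}

#' @rdname call_cycle_timings
#' @return `call_phases_cohort()`: the long per-frame label tibble for all
#'   cells.
#' @export
call_phases_cohort <- function(traces, thresholds, smooth_frames = 3) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ call_phases(.x, thresholds, smooth_frames)) |>
    dplyr::ungroup()
}
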