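#' Estimate reporter intensity thresholds from pooled single-cell intensities
#'
#' FUCCI phase calling needs one positivity threshold per reporter channel
#' (geminin-degron, "hgem", and PIP-degron, "pip"). Over a cohort, each
#' channel's pooled intensity distribution is bimodal: an "off" mode (degraded
#' reporter) and an "on" mode (accumulated reporter). The automatic rule places
#' the threshold at the antimode -- the deepest kernel-density minimum between
#' the two dominant density modes -- which separates the off and on
#' populations without per-line hand tuning. Manual values can be supplied
#' instead (or in addition) and pass through unchanged.
#'
#' @param hgem_samples,pip_samples Numeric vectors of pooled per-frame mean
#'   intensities (a.u., finite, >= 0) for the hGem and PIP channels. At least
#'   50 samples per channel are required for automatic estimation.
#' @param overrides Optional named list or vector with elements `hgem` and/or
#'   `pip` giving manual thresholds; a supplied channel skips estimation.
#' @param bw,n Bandwidth selector and grid size passed to [stats::density()].
#'
#' @return A one-row tibble with columns `hgem_thr`, `pip_thr` and `method`
#'   (`"auto"` if any channel was estimated, else `"manual"`).
#'
#' @details Reporter noise is multiplicative, so when all samples are
#'   strictly positive the density is estimated on the log scale (where the
#'   off and on modes have comparable widths) and the antimode is mapped
#'   back with `exp()`; samples containing zeros fall back to the linear
#'   scale. A channel whose density has fewer than two local maxima (after
#'   discarding modes below 5% of the global peak height) raises a
#'   `fuccikit_unimodal-channel` error asking for a manual override, since an
#'   antimode is undefined for a unimodal distribution.
#'
#' @examples
#' x <- c(rnorm(200, 1, 0.1), rnorm(200, 5, 0.3))
#' estimate_thresholds(x, x)
#' @export
estimate_thresholds <- function(hgem_samples, pip_samples, overrides = NULL,
                                bw = "nrd0", n = 4096) {
  ov <- as.list(overrides %||% list())
  thr <- c(hgem = NA_real_, pip = NA_real_)
  any_auto <- FALSE
  samples <- list(hgem = hgem_samples, pip = pip_samples)
  for (ch in c("hgem", "pip")) {
    if (!is.null(ov[[ch]])) {
      check_number(ov[[ch]], ch, lower = 0)
      if (ov[[ch]] <= 0 || !is.finite(ov[[ch]])) {
        stop_fucci("Manual thresholds must be strictly positive and finite.",
                   "bad-argument")
      }
      thr[[ch]] <- as.numeric(ov[[ch]])
    } else {
      thr[[ch]] <- channel_antimode(samples[[ch]], ch, bw = bw, n = n)
      any_auto <- TRUE
    }
  }
  tibble::tibble(hgem_thr = thr[["hgem"]], pip_thr = thr[["pip"]],
                 method = if (any_auto) "auto" else "manual")
}

# Antimode of a (putatively bimodal) sample: KDE on a fine grid, local maxima
# above 5% of the peak height are candidate modes, the two highest are the
# dominant modes, and the threshold is the density argmin strictly between
# them. Reporter noise is multiplicative, so for strictly positive samples
# the KDE runs on the log scale, where the two modes have comparable widths
# (and hence comparable heights even when one mode holds a small minority of
# frames); samples containing zeros are analysed on the linear scale.
channel_antimode <- function(x, name, bw = "nrd0", n = 4096) {
  check_finite_nonneg(x, name)
  if (length(x) < 50) {
    stop_fucci(sprintf(
      "Automatic thresholding for channel `%s` needs >= 50 samples (got %d).",
      name, length(x)), "too-few-samples")
  }
  if (diff(range(x)) == 0) {
    stop_fucci(sprintf(
      "Channel `%s` is constant; no antimode exists. Supply a manual override.",
      name), "unimodal-channel")
  }
  use_log <- min(x) > 0
  xs <- if (use_log) log(x) else x
  d <- stats::density(xs, bw = bw, n = n)
  y <- d$y
  k <- length(y)
  # strict-on-one-side local maxima; plateaus collapse to their first point
  is_max <- c(y[1] > y[2],
              y[2:(k - 1)] >= y[1:(k - 2)] & y[2:(k - 1)] > y[3:k],
              y[k] > y[k - 1])
  modes <- which(is_max & y >= 0.05 * max(y))
  if (length(modes) < 2) {
    stop_fucci(sprintf(
      "Channel `%s` looks unimodal (no antimode between two modes). Supply a manual override.",
      name), "unimodal-channel")
  }
  dominant <- sort(modes[order(y[modes], decreasing = TRUE)][1:2])
  between <- seq(dominant[1] + 1L, dominant[2] - 1L)
  cut_idx <- between[which.min(y[between])]
  thr <- d$x[cut_idx]
  if (use_log) thr <- exp(thr)
  # the KDE grid extends past the data; clamp inside the observed range
  min(max(thr, min(x) + .Machine$double.eps), max(x))
}
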