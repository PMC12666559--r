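#' DAPI intensity threshold marking the G1/S boundary
#'
#' Fixed-cell DNA staining is bimodal (2N vs replicating/4N cells). Given
#' the fraction of cells known to be in S/G2/M (e.g. from a parallel
#' live-imaging cohort at the same time point), the DAPI threshold is the
#' `(1 - sgm_fraction)` quantile of the per-cell DAPI intensities (linear
#' interpolation between order statistics), so that the proportion of cells
#' at or above the threshold reproduces the S/G2/M fraction.
#'
#' @param dapi_values Per-cell mean DAPI intensities (>= 10 cells).
#' @param sgm_fraction Known S/G2/M proportion, in `[0, 1)`.
#' @return The DAPI intensity threshold (same units as the input).
#' @examples
#' dapi_gs_threshold(1:10, 0.20) # 8.2
#' @export
dapi_gs_threshold <- function(dapi_values, sgm_fraction) {
  check_finite_nonneg(dapi_values, "dapi_values")
  if (length(dapi_values) < 10) {
    stop_fucci("Need >= 10 cells for a DAPI threshold.", "too-few-cells")
  }
  check_number(sgm_fraction, "sgm_fraction")
  if (sgm_fraction < 0 || sgm_fraction >= 1) {
    stop_fucci("`sgm_fraction` must be in [0, 1).", "bad-argument")
  }
  unname(stats::quantile(dapi_values, probs = 1 - sgm_fraction, type = 7))
}

#' Per-cell p-c-Myc / cyclin D1 ratio profile over DNA content
#'
#' Computes the ratio of phosphorylated c-Myc (Ser62) to cyclin D1 mean
#' intensity per cell, then bins cells by DAPI intensity and reports the
#' modal ratio ("vertex") per DAPI bin: the centre of the tallest bin of a
#' within-bin ratio histogram. A higher ratio means the cell carries more
#' p-c-Myc than cyclin D1.
#'
#' @param cells Tibble with columns `dapi`, `p_c_myc`, `ccnd1` (and
#'   optionally `cell_id`); intensities finite, >= 0.
#' @param dapi_bins Number of equal-width DAPI bins (default 10).
#' @param ratio_bins Number of equal-width histogram bins for the ratio
#'   within each DAPI bin (default 50). Ties in bin height go to the lowest
#'   bin.
#'
#' @return A list of class `ratio_profile`: `cells` (input rows with
#'   `ratio`, cyclin-D1-zero cells excluded with a message), `vertices`
#'   (tibble `dapi_bin`, `dapi_mid`, `n`, `vertex`), `n_excluded`.
#' @export
myc_cyclin_ratio_profile <- function(cells, dapi_bins = 10, ratio_bins = 50) {
  need <- c("dapi", "p_c_myc", "ccnd1")
  if (!all(need %in% names(cells))) {
    stop_fucci("`cells` needs columns dapi, p_c_myc, ccnd1.", "bad-argument")
  }
  for (col in need) check_finite_nonneg(cells[[col]], col)
  zero <- cells$ccnd1 == 0
  if (all(zero)) {
    stop_fucci("All cells have cyclin D1 intensity 0; no ratio is defined.",
               "degenerate-input")
  }
  if (any(zero)) {
    rlang::inform(sprintf(
      "Excluded %d cell(s) with cyclin D1 intensity 0.", sum(zero)))
  }
  d <- tibble::as_tibble(cells[!zero, ])
  d$ratio <- d$p_c_myc / d$ccnd1

  rng <- range(d$dapi)
  breaks <- if (diff(rng) == 0) c(rng[1] - 0.5, rng[1] + 0.5) else
    seq(rng[1], rng[2], length.out = dapi_bins + 1)
  d$dapi_bin <- cut(d$dapi, breaks = breaks, include.lowest = TRUE,
                    labels = FALSE)
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  vertices <- d |>
    dplyr::group_by(.data$dapi_bin) |>
    dplyr::summarise(n = dplyr::n(),
                     vertex = histogram_vertex(.data$ratio, ratio_bins),
                     .groups = "drop") |>
    dplyr::mutate(dapi_mid = mids[.data$dapi_bin], .after = "dapi_bin")
  out <- list(cells = d, vertices = vertices, n_excluded = sum(zero))
  class(out) <- "ratio_profile"
  out
}

# Centre of the tallest histogram bin over the within-group range; ties go
# to the lowest bin. A degenerate (constant) group returns its value.
histogram_vertex <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  top <- which.max(counts)  # which.max takes the first (lowest) on ties
  (breaks[top] + breaks[top + 1]) / 2
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("p-c-Myc / cyclin D1 ratio profile: %d cells (%d excluded), %d DAPI bins\n",
              nrow(x$cells), x$n_excluded, nrow(x$vertices)))
  print(x$vertices)
  invisible(x)
}

#' Pixelwise colocalization coefficients for two channels
#'
#' Computes the standard colocalization panel over (optionally masked)
#' pixel pairs: Pearson's r, Manders' M1/M2 (fraction of one channel's
#' intensity falling where the other channel is positive) and thresholded
#' Manders tM1/tM2 (fraction of one channel's above-threshold intensity
#' falling where the other channel exceeds its threshold).
#'
#' @param img_a,img_b Numeric matrices (or vectors) of identical shape,
#'   non-negative intensities.
#' @param thr_a,thr_b Intensity thresholds for the thresholded Manders
#'   coefficients.
#' @param mask Optional logical array of the same shape selecting the
#'   pixels to analyse.
#' @return A one-row tibble: `r`, `m1`, `m2`, `tm1`, `tm2`, `n_pixels`.
#' @examples
#' a <- matrix(runif(100), 10)
#' coloc_metrics(a, a, thr_a = 0.5, thr_b = 0.5)
#' @export
coloc_metrics <- function(img_a, img_b, thr_a, thr_b, mask = NULL) {
  if (!identical(dim(img_a) %||% length(img_a),
                 dim(img_b) %||% length(img_b))) {
    stop_fucci("`img_a` and `img_b` must have identical shape.",
               "shape-mismatch")
  }
  a <- as.numeric(img_a)
  b <- as.numeric(img_b)
  if (!is.null(mask)) {
    if (length(mask) != length(a)) {
      stop_fucci("`mask` must match the image shape.", "shape-mismatch")
    }
    a <- a[as.logical(mask)]
    b <- b[as.logical(mask)]
  }
  check_finite_nonneg(a, "img_a")
  check_finite_nonneg(b, "img_b")
  check_number(thr_a, "thr_a")
  check_number(thr_b, "thr_b")
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_fucci("Pearson's r needs >= 2 masked pixels with nonzero variance in both channels.",
               "degenerate-input")
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sel_a <- a > thr_a
  sel_b <- b > thr_b
  tibble::tibble(
    r = stats::cor(a, b),
    m1 = frac(sum(a[b > 0]), sum(a)),
    m2 = frac(sum(b[a > 0]), sum(b)),
    tm1 = frac(sum(a[sel_a & sel_b]), sum(a[sel_a])),
    tm2 = frac(sum(b[sel_a & sel_b]), sum(b[sel_b])),
    n_pixels = length(a)
  )
}

#' Percentage of positive cells
#'
#' Positive-cell fraction as used for senescence-associated
#' beta-galactosidase scoring: stained cells divided by total nuclei, as a
#' percentage.
#'
#' @param n_positive,n_total Counts; `n_total > 0`,
#'   `n_positive <= n_total`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' positive_fraction(30, 120) # 25
#' @export
positive_fraction <- function(n_positive, n_total) {
  check_number(n_positive, "n_positive", lower = 0)
  check_number(n_total, "n_total", lower = 0)
  if (n_total == 0) stop_fucci("`n_total` must be > 0.", "bad-argument")
  if (n_positive > n_total) {
    stop_fucci("`n_positive` cannot exceed `n_total`.", "bad-argument")
  }
  100 * n_positive / n_total
}
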