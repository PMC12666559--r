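#' Classify H3K27Ac peaks into promoters and enhancers
#'
#' Rule-based regulatory classification: an H3K27Ac peak whose centre lies
#' within 250 bp (inclusive) of the nearest transcription start site and
#' that does not overlap any H3K4me1 peak is a promoter; a peak whose
#' centre is more than 250 bp from every TSS and that overlaps an H3K4me1
#' peak is an enhancer; everything else (including K4me1-overlapping
#' TSS-proximal peaks) is labelled `other`.
#'
#' @param k27_peaks,k4me1_peaks Tibbles of peak intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open, as in BED). `k27_peaks`
#'   may carry a `region_id` column; one is created otherwise.
#' @param tss Tibble of TSS points with columns `chrom`, `pos` (0-based)
#'   and `gene`; a `strand` column is accepted and ignored (distances are
#'   strand-symmetric).
#' @param promoter_dist Maximum centre-to-TSS distance (bp, inclusive) for
#'   a promoter. Default 250.
#'
#' @return A tibble with one row per H3K27Ac peak: `region_id`, `chrom`,
#'   `start`, `end`, `center`, `label` (`promoter`/`enhancer`/`other`),
#'   `nearest_gene`, `tss_distance`. Peak centre is `floor((start+end)/2)`;
#'   nearest TSS is by absolute distance on the same chromosome, exact ties
#'   broken by lexicographic gene symbol. Peaks on chromosomes absent from
#'   the TSS table are labelled `other` with a warning.
#' @examples
#' k27 <- tibble::tibble(chrom = "chr1", start = 900, end = 1100)
#' tss <- tibble::tibble(chrom = "chr1", pos = 1100, gene = "GENE1")
#' classify_regions(k27, tibble::tibble(chrom = character(), start = integer(),
#'                                      end = integer()), tss)
#' @export
classify_regions <- function(k27_peaks, k4me1_peaks, tss,
                             promoter_dist = 250) {
  validate_intervals(k27_peaks, "k27_peaks")
  validate_intervals(k4me1_peaks, "k4me1_peaks", allow_empty = TRUE)
  if (!all(c("chrom", "pos", "gene") %in% names(tss)) || nrow(tss) == 0) {
    stop_fucci("`tss` needs non-empty columns chrom, pos, gene.",
               "bad-argument")
  }
  k27 <- tibble::as_tibble(k27_peaks)
  if (!"region_id" %in% names(k27)) {
    k27$region_id <- sprintf("region_%04d", seq_len(nrow(k27)))
  }
  k27$center <- floor((k27$start + k27$end) / 2)

  k27$k4me1_overlap <- overlaps_any(k27, k4me1_peaks)

  near <- nearest_tss(k27, tss)
  missing_chrom <- is.na(near$tss_distance)
  if (any(missing_chrom)) {
    rlang::warn(sprintf(
      "%d peak(s) lie on chromosomes absent from the TSS table; labelled 'other'.",
      sum(missing_chrom)))
  }
  out <- dplyr::bind_cols(k27, near)
  out$label <- dplyr::case_when(
    missing_chrom ~ "other",
    out$tss_distance <= promoter_dist & !out$k4me1_overlap ~ "promoter",
    out$tss_distance > promoter_dist & out$k4me1_overlap ~ "enhancer",
    .default = "other"
  )
  dplyr::select(out, "region_id", "chrom", "start", "end", "center",
                "label", "nearest_gene", "tss_distance")
}

validate_intervals <- function(x, name, allow_empty = FALSE) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    stop_fucci(sprintf("`%s` needs columns chrom, start, end.", name),
               "bad-argument")
  }
  if (nrow(x) == 0) {
    if (allow_empty) return(invisible(x))
    stop_fucci(sprintf("`%s` is empty.", name), "bad-argument")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop_fucci(sprintf(
      "`%s` intervals must satisfy 0 <= start < end (0-based half-open).",
      name), "bad-argument")
  }
  invisible(x)
}

# TRUE per row of `a` iff it shares >= 1 bp with any interval in `b`.
# 0-based half-open input -> 1-based closed IRanges.
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  gr_a <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1, b$end))
  GenomicRanges::countOverlaps(gr_a, gr_b, minoverlap = 1L) > 0
}

# Nearest TSS (same chromosome, absolute distance, lexicographic-gene ties).
nearest_tss <- function(peaks, tss) {
  res <- purrr::map(seq_len(nrow(peaks)), function(i) {
    cand <- tss[tss$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) {
      return(list(nearest_gene = NA_character_, tss_distance = NA_real_))
    }
    d <- abs(cand$pos - peaks$center[i])
    hit <- which(d == min(d))
    if (length(hit) > 1) hit <- hit[order(cand$gene[hit])][1]
    list(nearest_gene = cand$gene[hit], tss_distance = d[hit])
  })
  tibble::tibble(nearest_gene = purrr::map_chr(res, "nearest_gene"),
                 tss_distance = purrr::map_dbl(res, "tss_distance"))
}

#' Merge (union) a set of peak intervals
#'
#' Utility for combining peak sets called at several time points into one
#' non-redundant interval set before coverage comparison.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return A tibble of merged intervals in the same coordinate convention.
#' @export
merge_peaks <- function(peaks) {
  validate_intervals(peaks, "peaks")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end)))
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Differential (gained/lost) calls for classified regions
#'
#' Computes the coverage log2 fold change `log2((treat + c) / (ctrl + c))`
#' with pseudocount `c` and applies the rule set: promoters are `gained`
#' when the fold change exceeds `cov_threshold` (strictly) and `lost` below
#' its negative; enhancers additionally require the nearest gene's
#' expression log2 fold change to exceed `expr_threshold` in the same
#' direction. Regions labelled `other`, boundary values (thresholds are
#' strict), sign mismatches, and enhancers whose nearest gene lacks an
#' expression value (warned) are `unchanged`.
#'
#' @param regions Output of [classify_regions()].
#' @param coverage Tibble `region_id`, `coverage_treat`, `coverage_ctrl`
#'   (non-negative).
#' @param expr Tibble `gene`, `log2fc` (expression change, treat vs ctrl).
#'   May be `NULL` when no enhancers are present.
#' @param cov_threshold,expr_threshold Strict |log2FC| thresholds for
#'   coverage (default 0.3) and enhancer target expression (default 0.2).
#' @param pseudocount Added to both coverage values before the ratio
#'   (default 1).
#'
#' @return `regions` with added columns `log2fc_coverage`, `expr_log2fc`
#'   and `call` (`gained`/`lost`/`unchanged`).
#' @export
call_differential <- function(regions, coverage, expr = NULL,
                              cov_threshold = 0.3, expr_threshold = 0.2,
                              pseudocount = 1) {
  need <- c("region_id", "coverage_treat", "coverage_ctrl")
  if (!all(need %in% names(coverage))) {
    stop_fucci("`coverage` needs columns region_id, coverage_treat, coverage_ctrl.",
               "bad-argument")
  }
  check_finite_nonneg(coverage$coverage_treat, "coverage_treat")
  check_finite_nonneg(coverage$coverage_ctrl, "coverage_ctrl")
  d <- dplyr::left_join(regions, coverage, by = "region_id")
  if (anyNA(d$coverage_treat) || anyNA(d$coverage_ctrl)) {
    stop_fucci("Every region needs coverage in both conditions.",
               "bad-argument")
  }
  d$log2fc_coverage <- log2((d$coverage_treat + pseudocount) /
                              (d$coverage_ctrl + pseudocount))
  if (is.null(expr)) expr <- tibble::tibble(gene = character(),
                                            log2fc = numeric())
  d <- dplyr::left_join(d, dplyr::rename(expr, expr_log2fc = "log2fc"),
                        by = c(nearest_gene = "gene"))
  miss <- d$label == "enhancer" & is.na(d$expr_log2fc) &
    abs(d$log2fc_coverage) > cov_threshold
  if (any(miss)) {
    rlang::warn(sprintf(
      "%d enhancer(s) above the coverage threshold lack an expression value; called 'unchanged'.",
      sum(miss)))
  }
  cov_up <- d$log2fc_coverage > cov_threshold
  cov_dn <- d$log2fc_coverage < -cov_threshold
  expr_up <- !is.na(d$expr_log2fc) & d$expr_log2fc > expr_threshold
  expr_dn <- !is.na(d$expr_log2fc) & d$expr_log2fc < -expr_threshold
  d$call <- dplyr::case_when(
    d$label == "promoter" & cov_up ~ "gained",
    d$label == "promoter" & cov_dn ~ "lost",
    d$label == "enhancer" & cov_up & expr_up ~ "gained",
    d$label == "enhancer" & cov_dn & expr_dn ~ "lost",
    .default = "unchanged"
  )
  dplyr::select(d, -"coverage_treat", -"coverage_ctrl")
}
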