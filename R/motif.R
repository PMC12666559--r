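#' Count E-box (CANNTG) occurrences in a DNA sequence
#'
#' Scans for the canonical c-Myc binding motif CANNTG, where each N matches
#' any unambiguous base. Overlapping occurrences are all counted, and an N
#' in the *sequence* never matches any motif position (including the
#' wildcard positions), so ambiguous assembly bases cannot create hits.
#' CANNTG is its own reverse complement, so scanning one strand counts
#' every double-stranded site.
#'
#' @param sequence Character vector of DNA sequences over A/C/G/T/N
#'   (case-insensitive).
#' @return Integer vector of motif counts, one per input sequence.
#' @examples
#' scan_ebox("CACGTG")            # 1
#' scan_ebox("CACGTGCACGTG")      # 2
#' scan_ebox(c("CATG", "CANNTG")) # 0 0
#' @export
scan_ebox <- function(sequence) {
  if (!is.character(sequence)) {
    stop_fucci("`sequence` must be a character vector.", "bad-argument")
  }
  s <- toupper(sequence)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop_fucci("Sequences may contain only A, C, G, T or N.",
               "bad-alphabet")
  }
  # lookahead so overlapping sites are each counted
  vapply(s, function(si) {
    if (nchar(si) < 6) return(0L)
    m <- gregexpr("(?=CA[ACGT][ACGT]TG)", si, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' E-box enrichment of a foreground region set against a background
#'
#' Compares per-basepair E-box occurrence rates between two sequence sets
#' with a one-sided binomial test: the foreground count is tested against
#' the background per-position rate over the foreground's scannable
#' positions. A rate ratio (foreground / background) is reported alongside.
#'
#' @param fg_regions,bg_regions Character vectors of DNA sequences
#'   (foreground, e.g. promoter regions of one condition; background, e.g.
#'   all other regions).
#' @return A one-row tibble: `fg_count`, `fg_bp`, `bg_count`, `bg_bp`,
#'   `fg_rate`, `bg_rate`, `ratio`, `p_value` (one-sided, enrichment).
#'   Scannable positions per sequence are `max(nchar - 5, 0)` (motif start
#'   positions).
#' @export
ebox_enrichment <- function(fg_regions, bg_regions) {
  fg_counts <- scan_ebox(fg_regions)
  bg_counts <- scan_ebox(bg_regions)
  n_pos <- function(s) sum(pmax(nchar(s) - 5L, 0L))
  fg_bp <- n_pos(fg_regions)
  bg_bp <- n_pos(bg_regions)
  if (bg_bp == 0) {
    stop_fucci("Background set has no scannable positions.", "bad-argument")
  }
  fg_count <- sum(fg_counts)
  bg_count <- sum(bg_counts)
  if (fg_bp == 0) {
    # empty foreground: nothing to enrich
    return(tibble::tibble(fg_count = 0L, fg_bp = 0L, bg_count = bg_count,
                          bg_bp = bg_bp, fg_rate = 0, bg_rate = bg_count / bg_bp,
                          ratio = 0, p_value = 1))
  }
  fg_rate <- fg_count / fg_bp
  bg_rate <- bg_count / bg_bp
  p <- if (fg_count == 0) {
    1
  } else {
    stats::binom.test(fg_count, fg_bp, p = bg_rate,
                      alternative = "greater")$p.value
  }
  tibble::tibble(fg_count = fg_count, fg_bp = fg_bp,
                 bg_count = bg_count, bg_bp = bg_bp,
                 fg_rate = fg_rate, bg_rate = bg_rate,
                 ratio = if (bg_rate > 0) fg_rate / bg_rate else Inf,
                 p_value = p)
}
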