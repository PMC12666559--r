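# Independent brute-force oracles used across test files.

# all-pairs interval overlap (0-based half-open)
brute_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# position-by-position E-box scan
brute_scan_ebox <- function(s) {
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 6) return(0L)
  hits <- 0L
  for (i in 1:(n - 5)) {
    w <- chars[i:(i + 5)]
    if (w[1] == "C" && w[2] == "A" && w[3] %in% c("A", "C", "G", "T") &&
        w[4] %in% c("A", "C", "G", "T") && w[5] == "T" && w[6] == "G") {
      hits <- hits + 1L
    }
  }
  hits
}

# histogram argmax over the sample range, ties to the lowest bin
brute_vertex <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- integer(bins)
  for (v in x) {
    k <- findInterval(v, breaks, rightmost.closed = TRUE)
    k <- min(max(k, 1L), bins)
    counts[k] <- counts[k] + 1L
  }
  k <- which(counts == max(counts))[1]
  (breaks[k] + breaks[k + 1]) / 2
}

# clean periodic label sequence at 20-min frames starting t = 0
clean_labels <- function(n_g1 = 9, n_s = 9, n_g2m = 9, n_u = 9) {
  rep(c("G1", "S", "G2M", "U"), times = c(n_g1, n_s, n_g2m, n_u))
}

frame_times <- function(n, frame_h = 1 / 3) (seq_len(n) - 1) * frame_h

# snap a continuous event time to the first frame at or after it
snap_up <- function(t, frame_h = 1 / 3) frame_h * ceiling(t / frame_h - 1e-9)
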