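#' Scenario configuration for the FUCCI trace generator
#'
#' Bundles and validates every parameter of a simulated live-imaging
#' cohort: acquisition (frame interval, horizon), the cohort's
#' transition-time distributions (truncated normals), the coupling between
#' G1/S timing and downstream S/G2/M duration, reporter noise, and the
#' arrested-cell fraction.
#'
#' @param name Scenario label (recorded in outputs).
#' @param n_cells Number of cells to simulate.
#' @param frame_min Frame interval in minutes (must divide the horizon
#'   evenly; default 20).
#' @param horizon_h Observation horizon in hours (default 72).
#' @param t_g1s_mean,t_g1s_sd Mean/SD (h) of the G1/S transition time,
#'   drawn from a normal truncated at 0.
#' @param s_dur_mean,s_dur_sd Mean/SD (h) of the S-phase duration.
#' @param g2m_dur_mean,g2m_dur_sd Mean/SD (h) of the G2/M duration.
#' @param coupling `"independent"` (durations independent of G1/S time) or
#'   `"negative"` (total S/G2/M duration shrinks linearly with the
#'   standardized G1/S time).
#' @param coupling_strength Target correlation between `t_g1s` and
#'   `dur_sgm`, in `[-1, 0]`; used only for `coupling = "negative"`.
#' @param noise_sigma Multiplicative log-normal reporter noise, as a
#'   fraction of the reporter dynamic range (default 0.1).
#' @param arrest_fraction Proportion of cells that never leave G1.
#' @param seed Integer seed; every draw in [gen_fucci_traces()] flows from
#'   it.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom", n_cells = 100, frame_min = 20,
                            horizon_h = 72, t_g1s_mean = 19, t_g1s_sd = 7.2,
                            s_dur_mean = 13.5, s_dur_sd = 5.9,
                            g2m_dur_mean = 6.9, g2m_dur_sd = 1.5,
                            coupling = c("independent", "negative"),
                            coupling_strength = 0, noise_sigma = 0.1,
                            arrest_fraction = 0, seed = 1) {
  coupling <- match.arg(coupling)
  check_number(n_cells, "n_cells", lower = 0)
  check_number(frame_min, "frame_min", lower = 1)
  check_number(horizon_h, "horizon_h", lower = 1)
  if ((horizon_h * 60) %% frame_min != 0) {
    stop_fucci("`frame_min` must divide the horizon evenly.", "bad-argument")
  }
  for (nm in c("t_g1s_sd", "s_dur_sd", "g2m_dur_sd", "noise_sigma")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(arrest_fraction, "arrest_fraction", lower = 0)
  if (arrest_fraction > 1) {
    stop_fucci("`arrest_fraction` must be in [0, 1].", "bad-argument")
  }
  check_number(coupling_strength, "coupling_strength")
  if (coupling == "negative" &&
      (coupling_strength < -1 || coupling_strength > 0)) {
    stop_fucci("`coupling_strength` must be in [-1, 0] for negative coupling.",
               "infeasible-coupling")
  }
  cfg <- list(name = name, n_cells = as.integer(n_cells),
              frame_min = frame_min, horizon_h = horizon_h,
              t_g1s_mean = t_g1s_mean, t_g1s_sd = t_g1s_sd,
              s_dur_mean = s_dur_mean, s_dur_sd = s_dur_sd,
              g2m_dur_mean = g2m_dur_mean, g2m_dur_sd = g2m_dur_sd,
              coupling = coupling, coupling_strength = coupling_strength,
              noise_sigma = noise_sigma, arrest_fraction = arrest_fraction,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Load a packaged scenario
#'
#' The package ships YAML scenario files parameterized from the modeled
#' live-imaging cohorts: `"MCF7-control-HRG"` (heregulin-stimulated
#' control), `"MCF7-CDK4i"` (CDK4-inhibitor non-responders, negative
#' phase coupling), `"MCF7-AKTi"` and `"MCF7-MEKi"`.
#'
#' @param name Scenario name (case-insensitive; the shorthand `"control"`,
#'   `"cdk4i"`, `"akti"`, `"meki"` also works).
#' @param ... Overrides applied on top of the file values (e.g.
#'   `n_cells`, `seed`).
#' @return A `scenario_config`.
#' @examples
#' fucci_scenario("control", n_cells = 10, seed = 42)
#' @export
fucci_scenario <- function(name, ...) {
  short <- c(control = "MCF7-control-HRG", cdk4i = "MCF7-CDK4i",
             akti = "MCF7-AKTi", meki = "MCF7-MEKi")
  key <- tolower(name)
  file_name <- if (key %in% names(short)) short[[key]] else name
  path <- system.file("extdata", "scenarios", paste0(file_name, ".yaml"),
                      package = "fuccikit")
  if (path == "") {
    stop_fucci(sprintf("Unknown scenario '%s'.", name), "bad-argument")
  }
  vals <- yaml::read_yaml(path)
  vals[names(list(...))] <- list(...)
  do.call(scenario_config, vals)
}

#' Printed cohort statistics of the modeled inhibitor panel
#'
#' The per-cohort G1/S transition-time statistics (mean, SD, n of cells
#' completing M/G1 within 72 h) and phase-coupling regression results
#' (slope, intercept, Pearson r) that the scenario family is parameterized
#' from, plus the early/late S/G2/M duration summary of the CDK4i cohort
#' via [early_late_reference()].
#'
#' @return A tibble with one row per cohort (`control`, `cdk4i`, `akti`,
#'   `meki`).
#' @export
inhibitor_cohorts <- function() {
  tibble::tibble(
    cohort = c("control", "cdk4i", "akti", "meki"),
    n = c(96L, 52L, 42L, 75L),
    g1s_mean = c(24.7, 49.5, 39.6, 26.6),
    g1s_sd = c(5.7, 13.2, 14.8, 11.5),
    slope = c(1.0, 0.56, 1.0, 0.95),
    intercept = c(17, 37, 19, 17),
    pearson_r = c(0.84, 0.76, 0.91, 0.95)
  )
}

#' @rdname inhibitor_cohorts
#' @return `early_late_reference()`: a tibble with the early/late group
#'   S/G2/M duration means and SDs (h) for the CDK4i cohort.
#' @export
early_late_reference <- function() {
  tibble::tibble(group = c("early", "late"),
                 dur_sgm_mean = c(22.3, 15.8),
                 dur_sgm_sd = c(7.2, 2.4))
}

#' Generate a synthetic FUCCI trace cohort with ground truth
#'
#' Simulates per-cell two-channel reporter traces on the configured frame
#' grid. Per cell, the G1/S time is drawn from a normal truncated at zero;
#' S and G2/M durations are drawn independently and, for
#' `coupling = "negative"`, the total S/G2/M duration is shrunk linearly in
#' the standardized G1/S time to hit the target correlation
#' (`coupling_strength`), each phase floored at one frame. The PIP-degron
#' channel is high except during S; the geminin channel is high from G1/S
#' until M/G1 (APC/C-driven loss at mitotic exit). Both channels carry
#' multiplicative log-normal noise. A configured fraction of cells is
#' arrested in G1 and never transitions.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `traces` (long tibble `cell_id`, `time_h`, `hgem`,
#'   `pip`) and `truth` (per-cell tibble `cell_id`, `t_g1s`, `t_sg2`,
#'   `t_mg1`, `dur_s`, `dur_g2m`, `dur_sgm`, `arrested`, `complete`;
#'   transition times are `NA` for arrested cells, and `complete` means
#'   `t_mg1` falls within the horizon). Identical config and seed give
#'   byte-identical output.
#' @export
gen_fucci_traces <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_cells
  frame_h <- cfg$frame_min / 60
  times <- seq(0, cfg$horizon_h, by = frame_h)
  if (n == 0) {
    return(list(
      traces = tibble::tibble(cell_id = character(), time_h = numeric(),
                              hgem = numeric(), pip = numeric()),
      truth = tibble::tibble(cell_id = character(), t_g1s = numeric(),
                             t_sg2 = numeric(), t_mg1 = numeric(),
                             dur_s = numeric(), dur_g2m = numeric(),
                             dur_sgm = numeric(), arrested = logical(),
                             complete = logical())
    ))
  }
  withr::with_seed(cfg$seed, {
    arrested <- stats::runif(n) < cfg$arrest_fraction
    # truncated-at-0 normal via inverse CDF
    lo <- stats::pnorm(0, cfg$t_g1s_mean, cfg$t_g1s_sd)
    t_g1s <- stats::qnorm(stats::runif(n, lo, 1), cfg$t_g1s_mean, cfg$t_g1s_sd)
    raw_s <- stats::rnorm(n, cfg$s_dur_mean, cfg$s_dur_sd)
    raw_g <- stats::rnorm(n, cfg$g2m_dur_mean, cfg$g2m_dur_sd)
    if (cfg$coupling == "negative" && cfg$coupling_strength < 0) {
      rho <- cfg$coupling_strength
      mu_tot <- cfg$s_dur_mean + cfg$g2m_dur_mean
      sd_tot <- sqrt(cfg$s_dur_sd^2 + cfg$g2m_dur_sd^2)
      z <- (t_g1s - cfg$t_g1s_mean) / cfg$t_g1s_sd
      tot_raw <- raw_s + raw_g
      tot <- mu_tot + rho * sd_tot * z + sqrt(1 - rho^2) * (tot_raw - mu_tot)
      scale <- ifelse(tot_raw > 0, tot / tot_raw, 1)
      dur_s <- raw_s * scale
      dur_g2m <- raw_g * scale
    } else {
      dur_s <- raw_s
      dur_g2m <- raw_g
    }
    dur_s <- pmax(dur_s, frame_h)
    dur_g2m <- pmax(dur_g2m, frame_h)
    t_sg2 <- t_g1s + dur_s
    t_mg1 <- t_sg2 + dur_g2m

    t_g1s[arrested] <- NA_real_
    t_sg2[arrested] <- NA_real_
    t_mg1[arrested] <- NA_real_
    dur_s[arrested] <- NA_real_
    dur_g2m[arrested] <- NA_real_

    cell_id <- sprintf("cell_%04d", seq_len(n))
    truth <- tibble::tibble(
      cell_id = cell_id, t_g1s = t_g1s, t_sg2 = t_sg2, t_mg1 = t_mg1,
      dur_s = dur_s, dur_g2m = dur_g2m, dur_sgm = t_mg1 - t_g1s,
      arrested = arrested,
      complete = !arrested & !is.na(t_mg1) & t_mg1 <= cfg$horizon_h
    )

    low <- 0.1
    high <- 1.0
    nf <- length(times)
    grid <- tidyr::expand_grid(cell = seq_len(n), time_h = times)
    g1s_v <- t_g1s[grid$cell]
    sg2_v <- t_sg2[grid$cell]
    mg1_v <- t_mg1[grid$cell]
    in_s <- !is.na(g1s_v) & grid$time_h >= g1s_v & grid$time_h < sg2_v
    hgem_on <- !is.na(g1s_v) & grid$time_h >= g1s_v & grid$time_h < mg1_v
    pip_base <- ifelse(in_s, low, high)
    hgem_base <- ifelse(hgem_on, high, low)
    hgem <- hgem_base * exp(stats::rnorm(n * nf, 0, cfg$noise_sigma))
    pip <- pip_base * exp(stats::rnorm(n * nf, 0, cfg$noise_sigma))
    traces <- tibble::tibble(cell_id = cell_id[grid$cell],
                             time_h = grid$time_h, hgem = hgem, pip = pip)
    list(traces = traces, truth = truth)
  })
}

#' Configuration for the planted synthetic regulome
#'
#' @param n_promoters,n_enhancers,n_other Planted region counts per class.
#' @param n_gained,n_lost Planted differential regions, split as evenly as
#'   possible between promoters and enhancers.
#' @param fold Planted coverage fold change for gained (x `fold`) and lost
#'   (/ `fold`) regions; must clear the detection threshold after the
#'   pseudocount (default 1.5).
#' @param chrom,chrom_length Chromosome name and length (bp) the regions
#'   are placed on.
#' @param peak_width H3K27Ac peak width in bp (default 400).
#' @param n_ebox_promoter E-box copies planted in each promoter sequence
#'   (default 3).
#' @param seed Integer seed.
#' @return A validated list of class `regulome_config`.
#' @export
regulome_config <- function(n_promoters = 10, n_enhancers = 10, n_other = 5,
                            n_gained = 4, n_lost = 4, fold = 1.5,
                            chrom = "chr1", chrom_length = 1e6,
                            peak_width = 400, n_ebox_promoter = 3, seed = 1) {
  for (nm in c("n_promoters", "n_enhancers", "n_other", "n_gained", "n_lost",
               "n_ebox_promoter")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(fold, "fold", lower = 1)
  n_total <- n_promoters + n_enhancers + n_other
  if (n_total == 0) stop_fucci("No regions configured.", "bad-argument")
  if (n_gained + n_lost > n_promoters + n_enhancers) {
    stop_fucci("Planted gained+lost regions exceed promoter+enhancer count.",
               "bad-argument")
  }
  slot <- 4000
  if (chrom_length < (n_total + 1) * slot) {
    stop_fucci("`chrom_length` too small for the requested region count.",
               "bad-argument")
  }
  cfg <- list(n_promoters = as.integer(n_promoters),
              n_enhancers = as.integer(n_enhancers),
              n_other = as.integer(n_other), n_gained = as.integer(n_gained),
              n_lost = as.integer(n_lost), fold = fold, chrom = chrom,
              chrom_length = chrom_length, peak_width = as.integer(peak_width),
              slot = slot, n_ebox_promoter = as.integer(n_ebox_promoter),
              seed = as.integer(seed))
  class(cfg) <- "regulome_config"
  cfg
}

#' Generate a planted synthetic regulome
#'
#' Places promoter, enhancer and `other` regions in well-separated slots on
#' one chromosome so every class rule holds by construction: promoters sit
#' within 250 bp of a TSS with no H3K4me1; enhancers sit 500 bp from their
#' nearest TSS (> 250) under an overlapping H3K4me1 peak; `other` regions
#' are TSS-proximal *and* H3K4me1-overlapping (rules jointly unsatisfied).
#' Gained/lost regions receive coverage fold changes exceeding the
#' detection thresholds, with matching expression signs for enhancer
#' targets; promoter sequences carry planted E-box copies.
#'
#' @param cfg A [regulome_config()].
#' @return A list of tibbles: `k27`, `k4me1` (BED-style 0-based half-open
#'   intervals), `tss` (`chrom`, `pos`, `gene`, `strand`), `coverage`
#'   (`region_id`, `coverage_treat`, `coverage_ctrl`), `expr` (`gene`,
#'   `log2fc`), `sequences` (named character vector per `region_id`), and
#'   `truth` (`region_id`, planted `class` and `call`).
#' @export
gen_regulome <- function(cfg) {
  stopifnot(inherits(cfg, "regulome_config"))
  withr::with_seed(cfg$seed, {
    classes <- c(rep("promoter", cfg$n_promoters),
                 rep("enhancer", cfg$n_enhancers),
                 rep("other", cfg$n_other))
    n_total <- length(classes)
    classes <- sample(classes)
    centers <- cfg$slot / 2 + cfg$slot * (seq_len(n_total) - 1)
    half <- cfg$peak_width %/% 2
    region_id <- sprintf("region_%04d", seq_len(n_total))
    gene <- sprintf("GENE%04d", seq_len(n_total))

    k27 <- tibble::tibble(chrom = cfg$chrom, start = centers - half,
                          end = centers + half, region_id = region_id)
    is_enh <- classes == "enhancer"
    is_pro <- classes == "promoter"
    is_oth <- classes == "other"
    k4me1 <- tibble::tibble(chrom = cfg$chrom,
                            start = centers[is_enh | is_oth] - half + 100,
                            end = centers[is_enh | is_oth] + half + 100)
    tss_offset <- numeric(n_total)
    tss_offset[is_pro] <- sample(-200:200, sum(is_pro), replace = TRUE)
    tss_offset[is_enh] <- 500  # > 250 bp, unique nearest gene per enhancer
    tss_offset[is_oth] <- 0
    tss <- tibble::tibble(chrom = cfg$chrom, pos = centers + tss_offset,
                          gene = gene, strand = "+")

    # planted differential calls, split across promoter/enhancer classes
    call <- rep("unchanged", n_total)
    pro_idx <- which(is_pro)
    enh_idx <- which(is_enh)
    # even split with spill-over when one class lacks capacity
    alloc <- function(n, cap1, cap2) {
      a1 <- min(ceiling(n / 2), cap1)
      a2 <- min(n - a1, cap2)
      c(min(a1 + (n - a1 - a2), cap1), a2)
    }
    g <- alloc(cfg$n_gained, length(pro_idx), length(enh_idx))
    l <- alloc(cfg$n_lost, length(pro_idx) - g[1], length(enh_idx) - g[2])
    call[pro_idx[seq_len(g[1])]] <- "gained"
    call[enh_idx[seq_len(g[2])]] <- "gained"
    if (l[1] > 0) call[pro_idx[g[1] + seq_len(l[1])]] <- "lost"
    if (l[2] > 0) call[enh_idx[g[2] + seq_len(l[2])]] <- "lost"

    ctrl <- stats::runif(n_total, 8, 12)
    treat <- ctrl
    treat[call == "gained"] <- ctrl[call == "gained"] * cfg$fold
    treat[call == "lost"] <- ctrl[call == "lost"] / cfg$fold
    lfc <- log2((treat + 1) / (ctrl + 1))
    planted <- call != "unchanged"
    if (any(planted) && min(abs(lfc[planted])) <= 0.3) {
      stop_fucci("Planted `fold` does not clear the coverage threshold after the pseudocount.",
                 "infeasible-fold")
    }
    coverage <- tibble::tibble(region_id = region_id,
                               coverage_treat = treat, coverage_ctrl = ctrl)
    expr_lfc <- rep(0, n_total)
    expr_lfc[is_enh & call == "gained"] <- 0.5
    expr_lfc[is_enh & call == "lost"] <- -0.5
    expr <- tibble::tibble(gene = gene, log2fc = expr_lfc)

    seqs <- vapply(seq_len(n_total), function(i) {
      s <- sample(c("A", "C", "G", "T"), cfg$peak_width, replace = TRUE)
      if (is_pro[i] && cfg$n_ebox_promoter > 0) {
        at <- floor(seq(20, cfg$peak_width - 25,
                        length.out = cfg$n_ebox_promoter))
        for (p in at) s[p:(p + 5)] <- c("C", "A", "C", "G", "T", "G")
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- region_id

    list(k27 = k27, k4me1 = k4me1, tss = tss, coverage = coverage,
         expr = expr, sequences = seqs,
         truth = tibble::tibble(region_id = region_id, chrom = cfg$chrom,
                                start = centers - half, end = centers + half,
                                class = classes, call = call))
  })
}

#' Generate a bimodal single-cell immunofluorescence table
#'
#' Simulates per-cell DAPI (DNA content) intensities from a two-component
#' normal mixture -- a 2N (G1) mode with weight `1 - sgm_fraction` and a 4N
#' (S/G2/M) mode with weight `sgm_fraction` -- together with log-normal
#' p-c-Myc and cyclin D1 intensities.
#'
#' @param n_cells Number of cells.
#' @param sgm_fraction Weight of the 4N component, in `[0, 1]`.
#' @param dapi_modes Length-2 vector of 2N and 4N mode intensities
#'   (ascending; default `c(0.08, 0.16)`, bracketing the worked G1/S
#'   thresholds of fixed-cell MCF-7 data).
#' @param dapi_cv Coefficient of variation of each DAPI component
#'   (default 0.1).
#' @param ratio_params Named list of log-normal parameters for the marker
#'   channels: `myc_meanlog`, `myc_sdlog`, `ccnd1_meanlog`, `ccnd1_sdlog`.
#' @param seed Integer seed.
#' @return A tibble `cell_id`, `dapi`, `p_c_myc`, `ccnd1`, `sgm_true`
#'   (ground-truth component membership).
#' @export
gen_if_table <- function(n_cells, sgm_fraction = 0.224,
                         dapi_modes = c(0.08, 0.16), dapi_cv = 0.1,
                         ratio_params = list(myc_meanlog = 0, myc_sdlog = 0.3,
                                             ccnd1_meanlog = 0,
                                             ccnd1_sdlog = 0.3),
                         seed = 1) {
  check_number(n_cells, "n_cells", lower = 0)
  check_number(sgm_fraction, "sgm_fraction")
  if (sgm_fraction < 0 || sgm_fraction > 1) {
    stop_fucci("`sgm_fraction` must be in [0, 1].", "bad-argument")
  }
  if (length(dapi_modes) != 2 || dapi_modes[1] >= dapi_modes[2]) {
    stop_fucci("`dapi_modes` must be two ascending values (2N < 4N).",
               "bad-argument")
  }
  if (n_cells == 0) {
    return(tibble::tibble(cell_id = character(), dapi = numeric(),
                          p_c_myc = numeric(), ccnd1 = numeric(),
                          sgm_true = logical()))
  }
  withr::with_seed(seed, {
    sgm_true <- stats::runif(n_cells) < sgm_fraction
    mode <- ifelse(sgm_true, dapi_modes[2], dapi_modes[1])
    dapi <- abs(stats::rnorm(n_cells, mode, dapi_cv * mode))
    tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      dapi = dapi,
      p_c_myc = stats::rlnorm(n_cells, ratio_params$myc_meanlog,
                              ratio_params$myc_sdlog),
      ccnd1 = stats::rlnorm(n_cells, ratio_params$ccnd1_meanlog,
                            ratio_params$ccnd1_sdlog),
      sgm_true = sgm_true
    )
  })
}

#' Generate a correlated image pair for colocalization analysis
#'
#' Draws two pixel fields from a bivariate normal model with target Pearson
#' correlation `rho`, shifted and scaled to positive intensities (values
#' are floored at 0; with the default mean/sd the floor is ~5 SD away, so
#' the realized correlation matches the target to sampling error).
#'
#' @param shape Length-2 integer vector (rows, cols).
#' @param rho Target correlation in `[-1, 1]`.
#' @param mean,sd Intensity location/scale of both channels.
#' @param seed Integer seed.
#' @return A list with matrices `a` and `b`.
#' @export
gen_coloc_pair <- function(shape = c(100, 100), rho, mean = 0.5, sd = 0.1,
                           seed = 1) {
  check_number(rho, "rho")
  if (abs(rho) > 1) stop_fucci("`rho` must be in [-1, 1].", "bad-argument")
  if (length(shape) != 2 || any(shape < 1)) {
    stop_fucci("`shape` must be two positive integers.", "bad-argument")
  }
  withr::with_seed(seed, {
    npx <- prod(shape)
    a0 <- stats::rnorm(npx)
    e <- stats::rnorm(npx)
    b0 <- rho * a0 + sqrt(1 - rho^2) * e
    a <- pmax(mean + sd * a0, 0)
    b <- pmax(mean + sd * b0, 0)
    list(a = matrix(a, shape[1], shape[2]), b = matrix(b, shape[1], shape[2]))
  })
}
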