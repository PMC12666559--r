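thr1 <- c(hgem_thr = 1, pip_thr = 1)

test_that("the reporter rule table maps joint positivity to phases", {
  cases <- tibble::tribble(
    ~hgem, ~pip, ~want,
    0.2,   5,    "G1",   # PIP-positive only
    5,     0.2,  "S",    # hGem-positive only
    5,     5,    "G2M",  # both positive
    0.2,   0.2,  "U",    # both sub-threshold
    1,     1,    "U"     # exactly at threshold is not positive
  )
  tr <- tibble::tibble(time_h = seq_len(nrow(cases)) / 3,
                       hgem = cases$hgem, pip = cases$pip)
  got <- call_phases(tr, thr1, smooth_frames = 1)
  expect_identical(got$label, cases$want)
})

test_that("every finite intensity pair gets exactly one of the four labels", {
  set.seed(42)
  n <- 400
  tr <- tibble::tibble(time_h = seq_len(n) / 3,
                       hgem = runif(n, 0, 3), pip = runif(n, 0, 3))
  lab <- call_phases(tr, thr1, smooth_frames = 1)$label
  expect_true(all(lab %in% c("G1", "S", "G2M", "U")))
  expect_length(lab, n)
})

test_that("phase labels are invariant to joint channel/threshold rescaling", {
  set.seed(11)
  n <- 200
  tr <- tibble::tibble(time_h = seq_len(n) / 3,
                       hgem = runif(n, 0, 3), pip = runif(n, 0, 3))
  base <- call_phases(tr, c(hgem_thr = 1.2, pip_thr = 0.8))
  for (k in c(0.25, 7, 1000)) {
    scaled <- dplyr::mutate(tr, hgem = hgem * k)
    got <- call_phases(scaled, c(hgem_thr = 1.2 * k, pip_thr = 0.8))
    expect_identical(got$label, base$label)
  }
})

test_that("label median filter removes flicker and breaks ties causally", {
  lab <- c("G1", "G1", "S", "G1", "G1", "G1")
  tr <- tibble::tibble(time_h = seq_along(lab) / 3,
                       hgem = ifelse(lab == "S", 5, 0.2),
                       pip = ifelse(lab == "S", 0.2, 5))
  expect_identical(call_phases(tr, thr1, smooth_frames = 3)$label,
                   rep("G1", 6))
  # 2-2 tie inside a width-3 window keeps the prior frame's label
  lab2 <- c("G1", "G1", "S", "S")
  tr2 <- tibble::tibble(time_h = seq_along(lab2) / 3,
                        hgem = ifelse(lab2 == "S", 5, 0.2),
                        pip = ifelse(lab2 == "S", 0.2, 5))
  got <- call_phases(tr2, thr1, smooth_frames = 3)$label
  expect_identical(got[2], "G1")
})

test_that("a clean G1->S->G2M->U sequence yields exact transition times", {
  lab <- clean_labels()
  tt <- extract_timings(lab, frame_times(length(lab)))
  expect_true(tt$complete)
  expect_identical(tt$status, "complete")
  expect_equal(tt$t_g1s, 3.0)
  expect_equal(tt$t_sg2, 6.0)
  expect_equal(tt$t_mg1, 9.0)
  expect_equal(tt$dur_sgm, tt$t_mg1 - tt$t_g1s)
  expect_equal(tt$dur_s, 3.0)
  expect_equal(tt$dur_g2m, 3.0)
})

test_that("arrested, pre-cycling and non-canonical traces are flagged", {
  n <- 216
  arrested <- extract_timings(rep("G1", n), frame_times(n))
  expect_false(arrested$complete)
  expect_identical(arrested$status, "incomplete")
  expect_true(is.na(arrested$t_g1s))
  expect_true(is.na(arrested$t_mg1))

  pre <- extract_timings(rep(c("S", "G2M", "U"), each = 9), frame_times(27))
  expect_identical(pre$status, "pre-cycling")

  skip_s <- extract_timings(rep(c("G1", "G2M"), each = 9), frame_times(18))
  expect_identical(skip_s$status, "non-canonical")

  back <- extract_timings(rep(c("G1", "S", "G1"), each = 9), frame_times(27))
  expect_identical(back$status, "non-canonical")
})

test_that("sub-dwell flicker does not trigger or break transitions", {
  lab <- c(rep("G1", 8), "S", rep("G1", 8), rep("S", 9), rep("G2M", 9),
           rep("U", 9))
  tt <- extract_timings(lab, frame_times(length(lab)))
  expect_true(tt$complete)
  # the single-frame S at frame 9 is ignored; S starts at frame 18 (0-based 17)
  expect_equal(tt$t_g1s, 17 / 3)
})

test_that("noise-free generator traces are recovered exactly to the frame", {
  cfg <- scenario_config(n_cells = 25, noise_sigma = 0, seed = 3)
  sim <- gen_fucci_traces(cfg)
  tt <- call_cycle_timings(sim$traces,
                           thresholds = c(hgem_thr = 0.5, pip_thr = 0.5),
                           smooth_frames = 1, min_dwell_frames = 1)
  j <- dplyr::inner_join(tt, sim$truth, by = "cell_id",
                         suffix = c("", ".true"))
  done <- j[j$complete.true, ]
  expect_gt(nrow(done), 15)
  expect_equal(done$t_g1s, snap_up(done$t_g1s.true), tolerance = 1e-12)
  expect_equal(done$t_sg2, snap_up(done$t_sg2.true), tolerance = 1e-12)
  expect_equal(done$t_mg1, snap_up(done$t_mg1.true), tolerance = 1e-12)
})

test_that("noisy traces are recovered within one frame of ground truth", {
  cfg <- scenario_config(n_cells = 40, noise_sigma = 0.1, seed = 11)
  sim <- gen_fucci_traces(cfg)
  tt <- call_cycle_timings(sim$traces)
  j <- dplyr::inner_join(dplyr::filter(tt, complete),
                         dplyr::filter(sim$truth, complete),
                         by = "cell_id", suffix = c("", ".true"))
  expect_gt(nrow(j), 30)
  frame_h <- 1 / 3
  expect_true(all(abs(j$t_g1s - snap_up(j$t_g1s.true)) <= frame_h + 1e-9))
  expect_true(all(abs(j$t_sg2 - snap_up(j$t_sg2.true)) <= frame_h + 1e-9))
  expect_true(all(abs(j$t_mg1 - snap_up(j$t_mg1.true)) <= frame_h + 1e-9))
  # recovered transitions are strictly ordered for every complete cell
  expect_true(all(j$t_g1s < j$t_sg2 & j$t_sg2 < j$t_mg1))
})

test_that("most complete cells survive phase calling at 15% noise", {
  cfg <- scenario_config(n_cells = 60, noise_sigma = 0.15, seed = 21)
  sim <- gen_fucci_traces(cfg)
  tt <- call_cycle_timings(sim$traces)
  truth_complete <- sim$truth$cell_id[sim$truth$complete]
  recovered <- tt$cell_id[tt$complete]
  expect_gte(mean(truth_complete %in% recovered), 0.95)
})
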