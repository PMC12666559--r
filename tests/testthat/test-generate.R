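test_that("scenario configs validate their parameters", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(frame_min = 25), class = "fuccikit_bad-argument")
  expect_error(scenario_config(arrest_fraction = 1.2),
               class = "fuccikit_bad-argument")
  expect_error(scenario_config(coupling = "negative", coupling_strength = 0.5),
               class = "fuccikit_infeasible-coupling")
  expect_error(scenario_config(t_g1s_sd = -1), class = "fuccikit_bad-argument")
})

test_that("packaged scenarios load with overridable parameters", {
  for (nm in c("control", "cdk4i", "akti", "meki")) {
    cfg <- fucci_scenario(nm)
    expect_s3_class(cfg, "scenario_config")
    expect_equal(cfg$frame_min, 20)
    expect_equal(cfg$horizon_h, 72)
  }
  expect_equal(fucci_scenario("MCF7-control-HRG")$t_g1s_mean, 19.0)
  expect_equal(fucci_scenario("cdk4i")$t_g1s_mean, 49.5)
  expect_identical(fucci_scenario("cdk4i")$coupling, "negative")
  over <- fucci_scenario("control", n_cells = 7, seed = 99)
  expect_equal(over$n_cells, 7L)
  expect_equal(over$seed, 99L)
  expect_error(fucci_scenario("nope"), class = "fuccikit_bad-argument")
})

test_that("an empty cohort yields empty, well-typed tables", {
  sim <- gen_fucci_traces(scenario_config(n_cells = 0))
  expect_equal(nrow(sim$traces), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_named(sim$traces, c("cell_id", "time_h", "hgem", "pip"))
})

test_that("ground-truth G1/S times match the configured distribution", {
  cfg <- scenario_config(n_cells = 200, seed = 1)
  sim <- gen_fucci_traces(cfg)
  m <- mean(sim$truth$t_g1s)
  sem <- sd(sim$truth$t_g1s) / sqrt(nrow(sim$truth))
  expect_lt(abs(m - cfg$t_g1s_mean), 3 * sem)
})

test_that("a short horizon leaves almost every cell incomplete", {
  cfg <- scenario_config(n_cells = 100, horizon_h = 10, t_g1s_mean = 19,
                         seed = 2)
  sim <- gen_fucci_traces(cfg)
  expect_gte(mean(!sim$truth$complete), 0.95)
})

test_that("generators are byte-deterministic at fixed seed and config", {
  cfg <- fucci_scenario("cdk4i", n_cells = 30)
  expect_identical(gen_fucci_traces(cfg), gen_fucci_traces(cfg))
  rcfg <- regulome_config(seed = 5)
  expect_identical(gen_regulome(rcfg), gen_regulome(rcfg))
  expect_identical(gen_if_table(100, seed = 3), gen_if_table(100, seed = 3))
  expect_identical(gen_coloc_pair(c(20, 20), 0.3, seed = 6),
                   gen_coloc_pair(c(20, 20), 0.3, seed = 6))
  # a different seed changes the draw
  expect_false(identical(gen_if_table(100, seed = 3),
                         gen_if_table(100, seed = 4)))
})

test_that("negative coupling hits the target correlation at n = 200", {
  cfg <- fucci_scenario("cdk4i", n_cells = 200, arrest_fraction = 0)
  sim <- gen_fucci_traces(cfg)
  got <- cor(sim$truth$t_g1s, sim$truth$dur_sgm)
  expect_lt(abs(got - cfg$coupling_strength), 0.1)
})

test_that("arrested cells never transition and stay in G1", {
  cfg <- scenario_config(n_cells = 40, arrest_fraction = 1, seed = 9)
  sim <- gen_fucci_traces(cfg)
  expect_true(all(sim$truth$arrested))
  expect_true(all(is.na(sim$truth$t_g1s)))
  labs <- call_phases_cohort(sim$traces, c(hgem_thr = 0.4, pip_thr = 0.4))
  expect_gte(mean(labs$label == "G1"), 0.99)
})

test_that("regulome configs validate placement feasibility", {
  expect_error(regulome_config(n_promoters = 0, n_enhancers = 0, n_other = 0),
               class = "fuccikit_bad-argument")
  expect_error(regulome_config(n_gained = 20, n_lost = 10),
               class = "fuccikit_bad-argument")
  expect_error(regulome_config(chrom_length = 1000),
               class = "fuccikit_bad-argument")
  expect_error(gen_regulome(regulome_config(fold = 1.05)),
               class = "fuccikit_infeasible-fold")
})

test_that("planted class counts equal the configuration", {
  cfg <- regulome_config(n_promoters = 6, n_enhancers = 7, n_other = 0,
                         n_gained = 3, n_lost = 2, seed = 4)
  reg <- gen_regulome(cfg)
  expect_equal(sum(reg$truth$class == "promoter"), 6)
  expect_equal(sum(reg$truth$class == "enhancer"), 7)
  expect_equal(sum(reg$truth$call == "gained"), 3)
  expect_equal(sum(reg$truth$call == "lost"), 2)
  expect_equal(nrow(reg$k27), 13)
  # promoter sequences carry the planted E-boxes
  pro <- reg$truth$region_id[reg$truth$class == "promoter"]
  expect_true(all(scan_ebox(reg$sequences[pro]) >= 3))
})

test_that("IF tables honour mixture weights and edge cases", {
  expect_equal(nrow(gen_if_table(0)), 0)
  uni <- gen_if_table(300, sgm_fraction = 0, seed = 5)
  expect_false(any(uni$sgm_true))
  mix <- gen_if_table(4000, sgm_fraction = 0.224, seed = 2)
  ci99 <- 2.576 * sqrt(0.224 * 0.776 / 4000)
  expect_lt(abs(mean(mix$sgm_true) - 0.224), ci99)
  expect_error(gen_if_table(100, sgm_fraction = 1.5),
               class = "fuccikit_bad-argument")
  expect_error(gen_if_table(100, dapi_modes = c(0.2, 0.1)),
               class = "fuccikit_bad-argument")
})

test_that("coloc pairs reach the extremes and stay near zero at rho = 0", {
  one <- gen_coloc_pair(c(50, 50), rho = 1, seed = 4)
  expect_equal(cor(as.numeric(one$a), as.numeric(one$b)), 1.0)
  neg <- gen_coloc_pair(c(50, 50), rho = -1, seed = 4)
  expect_equal(cor(as.numeric(neg$a), as.numeric(neg$b)), -1.0,
               tolerance = 1e-12)
  zero <- gen_coloc_pair(c(100, 100), rho = 0, seed = 4)
  expect_lt(abs(cor(as.numeric(zero$a), as.numeric(zero$b))), 0.05)
  expect_error(gen_coloc_pair(c(10, 10), rho = 1.2),
               class = "fuccikit_bad-argument")
})
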