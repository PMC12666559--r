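empty_bed <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer())

test_that("the promoter/enhancer rule table classifies canonical cases", {
  k27 <- tibble::tibble(
    chrom = "chr1",
    start = c(900, 5800, 0, 2000),
    end = c(1100, 6200, 200, 2500),
    region_id = c("prom", "enh", "oth", "boundary")
  )
  # centers: 1000, 6000, 100, 2250
  k4 <- tibble::tibble(chrom = "chr1", start = c(5900, 50), end = c(6100, 150))
  tss <- tibble::tibble(chrom = "chr1", pos = c(1100, 200, 2500),
                        gene = c("GA", "GB", "GC"))
  got <- classify_regions(k27, k4, tss)

  expect_identical(got$label[got$region_id == "prom"], "promoter")
  expect_equal(got$tss_distance[got$region_id == "prom"], 100)

  expect_identical(got$label[got$region_id == "enh"], "enhancer")
  expect_gt(got$tss_distance[got$region_id == "enh"], 250)

  # TSS-proximal but K4me1-overlapping: rules jointly unsatisfied
  expect_identical(got$label[got$region_id == "oth"], "other")

  # centre exactly 250 bp from the TSS is still a promoter (inclusive)
  expect_identical(got$label[got$region_id == "boundary"], "promoter")
  expect_equal(got$tss_distance[got$region_id == "boundary"], 250)

  # one label per peak
  expect_equal(nrow(got), nrow(k27))
  expect_true(all(got$label %in% c("promoter", "enhancer", "other")))
})

test_that("peaks on chromosomes without TSS annotation fall back to other", {
  k27 <- tibble::tibble(chrom = c("chr1", "chr9"), start = c(900, 900),
                        end = c(1100, 1100))
  tss <- tibble::tibble(chrom = "chr1", pos = 1000, gene = "GA")
  expect_warning(got <- classify_regions(k27, empty_bed, tss),
                 "absent from the TSS table")
  expect_identical(got$label[2], "other")
  expect_true(is.na(got$nearest_gene[2]))
})

test_that("exact nearest-TSS ties break by lexicographic gene symbol", {
  k27 <- tibble::tibble(chrom = "chr1", start = 900, end = 1100) # centre 1000
  tss <- tibble::tibble(chrom = "chr1", pos = c(900, 1100),
                        gene = c("ZZZ", "AAA"))
  got <- classify_regions(k27, empty_bed, tss)
  expect_identical(got$nearest_gene, "AAA")
  expect_equal(got$tss_distance, 100)
})

test_that("interval overlap matches an all-pairs brute-force check", {
  set.seed(13)
  for (rep in 1:3) {
    a <- tibble::tibble(chrom = "chr1",
                        start = sample(0:5000, 80))
    a$end <- a$start + sample(10:400, 80, replace = TRUE)
    b <- tibble::tibble(chrom = "chr1", start = sample(0:5000, 60))
    b$end <- b$start + sample(10:400, 60, replace = TRUE)
    expect_identical(fuccikit:::overlaps_any(a, b), brute_overlap_any(a, b))
  }
})

test_that("merge_peaks unions touching and overlapping intervals", {
  p <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(0, 5, 30, 0), end = c(10, 20, 40, 5))
  m <- merge_peaks(p)
  expect_equal(m$start[m$chrom == "chr1"], c(0, 30))
  expect_equal(m$end[m$chrom == "chr1"], c(20, 40))
  expect_equal(nrow(m), 3)
})

test_that("differential calls follow the strict fold-change rules", {
  regions <- tibble::tibble(
    region_id = c("p1", "p2", "e1", "e2", "e3", "o1"),
    chrom = "chr1", start = 0, end = 1, center = 0,
    label = c("promoter", "promoter", "enhancer", "enhancer", "enhancer",
              "other"),
    nearest_gene = c("GA", "GB", "GC", "GD", "GE", "GF"),
    tss_distance = c(10, 10, 500, 500, 500, 10)
  )
  enh_treat <- (10 + 1) * 2^-0.5 - 1 # coverage log2fc exactly -0.5
  coverage <- tibble::tibble(
    region_id = regions$region_id,
    coverage_treat = c(13.2, 5, enh_treat, enh_treat, enh_treat, 50),
    coverage_ctrl = c(9, 10, 10, 10, 10, 10)
  )
  expr <- tibble::tibble(gene = c("GC", "GD"), log2fc = c(-0.25, 0.25))
  expect_warning(got <- call_differential(regions, coverage, expr),
                 "lack an expression value")

  # hand-computed: log2(14.2/10) = 0.5059 > 0.3
  expect_equal(got$log2fc_coverage[got$region_id == "p1"], log2(14.2 / 10))
  expect_identical(got$call[got$region_id == "p1"], "gained")
  # clear loss on a promoter: log2(6/11) = -0.87 < -0.3
  expect_identical(got$call[got$region_id == "p2"], "lost")
  # enhancer: coverage down with expression down -> lost
  expect_identical(got$call[got$region_id == "e1"], "lost")
  # same coverage, expression sign mismatch -> unchanged
  expect_identical(got$call[got$region_id == "e2"], "unchanged")
  # no expression value for the nearest gene -> unchanged (warned above)
  expect_identical(got$call[got$region_id == "e3"], "unchanged")
  # non-regulatory regions are never called
  expect_identical(got$call[got$region_id == "o1"], "unchanged")
})

test_that("fold changes exactly at the threshold stay unchanged", {
  # ratio exactly 2 gives log2fc exactly 1.0 in floating point; with the
  # threshold set to 1 the strict inequality must leave the call unchanged
  regions <- tibble::tibble(region_id = "p", chrom = "chr1", start = 0,
                            end = 1, center = 0, label = "promoter",
                            nearest_gene = "GA", tss_distance = 10)
  coverage <- tibble::tibble(region_id = "p", coverage_treat = 21,
                             coverage_ctrl = 10) # (21+1)/(10+1) = 2
  got <- call_differential(regions, coverage, cov_threshold = 1)
  expect_equal(got$log2fc_coverage, 1.0)
  expect_identical(got$call, "unchanged")
  over <- call_differential(regions, coverage, cov_threshold = 0.99)
  expect_identical(over$call, "gained")
})

test_that("the planted regulome is recovered exactly without noise", {
  cfg <- regulome_config(n_promoters = 10, n_enhancers = 10, n_other = 5,
                         n_gained = 5, n_lost = 4, seed = 8)
  reg <- gen_regulome(cfg)
  cl <- classify_regions(reg$k27, reg$k4me1, reg$tss)
  j <- dplyr::inner_join(cl, reg$truth, by = "region_id")
  expect_equal(nrow(j), 25)
  expect_identical(j$label, j$class)

  calls <- call_differential(cl, reg$coverage, reg$expr)
  j2 <- dplyr::inner_join(calls, reg$truth, by = "region_id")
  expect_identical(j2$call.x, j2$call.y)
  expect_equal(sum(j2$call.x == "gained"), 5)
  expect_equal(sum(j2$call.x == "lost"), 4)
})

test_that("planted promoters at fold 1.5 are called gained (log2 ~ 0.585)", {
  cfg <- regulome_config(n_promoters = 5, n_enhancers = 0, n_other = 0,
                         n_gained = 5, n_lost = 0, fold = 1.5, seed = 2)
  reg <- gen_regulome(cfg)
  cl <- classify_regions(reg$k27, reg$k4me1, reg$tss)
  calls <- call_differential(cl, reg$coverage, reg$expr)
  expect_equal(sum(calls$call == "gained"), 5)
})
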