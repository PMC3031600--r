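# IHC morphometry: Otsu threshold, labeling, area measurement, comparison.

test_that("Otsu separates a clean bimodal image and rejects constants", {
  img <- matrix(40, 50, 50)
  img[10:20, 10:20] <- 200
  thr <- otsu_threshold(img)
  expect_gt(thr, 40); expect_lt(thr, 200)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")
})

test_that("labeling finds well-separated disks with 8-connectivity", {
  sim <- gen_ihc(ihc_sim_spec(n_vessels = 10, px_um = 1, area_mean_um2 = 40,
                              area_sd_um2 = 10, noise_sd = 0, seed = 3))
  seg <- segment_vessels(sim$field)
  expect_equal(max(seg$labels), 10L)
  # blank field -> no objects (one off pixel keeps Otsu defined; the
  # resulting 1 px component falls below min_area_um2)
  blank <- gen_ihc(ihc_sim_spec(n_vessels = 0, px_um = 1, noise_sd = 0,
                                seed = 1))
  blank$field$image[1, 1] <- blank$field$image[1, 1] + 1
  expect_equal(max(segment_vessels(blank$field)$labels), 0L)
  # diagonal contact merges under 8-connectivity
  fg <- matrix(FALSE, 4, 4); fg[1, 1] <- TRUE; fg[2, 2] <- TRUE
  expect_equal(max(label_components(fg)), 1L)
})

test_that("measured disk area approximates the analytic area", {
  # radius 2.5 um disk at 0.5 um/px: pixel count * px^2 within 10% of pi*2.5^2
  sim <- gen_ihc(ihc_sim_spec(n_vessels = 1, area_mean_um2 = pi * 2.5^2,
                              area_sd_um2 = 0, px_um = 0.5, noise_sd = 0,
                              seed = 5))
  fs <- measure_fields(segment_vessels(sim$field), 0.5)
  expect_equal(fs$n_vessels, 1L)
  expect_rel_error(fs$mean_area_um2, pi * 2.5^2, 0.1)
})

test_that("area measurement converges as pixels shrink", {
  # < 2% error at 0.25 um/px for radius >= 2 um objects
  sim <- gen_ihc(ihc_sim_spec(n_vessels = 6, area_mean_um2 = 20,
                              area_sd_um2 = 4, px_um = 0.25, noise_sd = 0,
                              field_um = 200, seed = 6))
  fs <- measure_fields(segment_vessels(sim$field), 0.25)
  expect_equal(fs$n_vessels, 6L)
  expect_rel_error(mean(fs$areas_um2), mean(sim$truth$area_um2), 0.02)
})

test_that("field summaries satisfy their contracts", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:6] <- 1L   # 10 px
  lab[6:9, 2:6] <- 2L   # 20 px
  lab[2:7, 8:9] <- 3L   # 12 px... adjust to get {10,20,30}
  lab[2:7, 8:9] <- 0L
  lab[1:10, 8:10] <- 3L # 30 px
  fs <- measure_fields(lab, px_um = 1)
  expect_equal(fs$n_vessels, 3L)
  expect_equal(sort(fs$areas_um2), c(10, 20, 30))
  expect_equal(fs$mean_area_um2, 20)
  # empty label map: explicit empty summary
  fs0 <- measure_fields(matrix(0L, 5, 5), px_um = 1)
  expect_equal(fs0$n_vessels, 0L)
  expect_true(is.na(fs0$mean_area_um2))
  expect_length(fs0$areas_um2, 0L)
})

test_that("count recovery is exact for generator fields above min area", {
  for (s in 1:4) {
    sim <- gen_ihc(ihc_sim_spec(n_vessels = 15, px_um = 1,
                                area_mean_um2 = 25, area_sd_um2 = 8,
                                seed = s))
    fs <- measure_fields(segment_vessels(sim$field), 1)
    expect_equal(fs$n_vessels, 15L)
  }
})

test_that("group comparison flags distinct area distributions", {
  mk <- function(mean_um2, sd_um2, seeds) {
    lapply(seeds, function(s) {
      sim <- gen_ihc(ihc_sim_spec(px_um = 1, n_vessels = 15,
                                  area_mean_um2 = mean_um2,
                                  area_sd_um2 = sd_um2, seed = s))
      measure_fields(segment_vessels(sim$field), 1)
    })
  }
  saline <- mk(30.83, 12, 1:4)
  dex <- mk(16.45, 6, 5:8)
  cmp <- compare_vessel_area(saline, dex)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$mean_a, cmp$mean_b)
  # identical groups -> p = 1
  same <- mk(20, 5, 1:3)
  expect_equal(compare_vessel_area(same, same)$p, 1)
})
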