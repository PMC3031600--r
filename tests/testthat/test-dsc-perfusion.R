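# DSC perfusion: Delta-R2* conversion, trapezoidal CBV integration with a
# Gamma-function oracle, rCBV, Bonferroni threshold, display normalization.

make_series <- function(curve, te_s = 0.0345, dt_s = 1.02, s0 = 1000,
                        baseline = 1:5) {
  sig <- array(rep(s0 * exp(-te_s * curve), each = 8),
               c(2, 2, 2, length(curve)))
  dsc_series(sig, te_s = te_s, dt_s = dt_s, baseline_idx = baseline)
}

test_that("Delta-R2* inverts the signal equation", {
  # flat signal -> zero curve
  flat <- make_series(rep(0, 20))
  expect_equal(max(abs(compute_delta_r2star(flat)$dr2s)), 0)

  # S = S0 * exp(-0.345) at TE = 34.5 ms -> 10 1/s; S/S0 = 1/2 -> ln2/TE
  curve <- c(rep(0, 5), 10, log(2) / 0.0345, rep(0, 3))
  st <- compute_delta_r2star(make_series(curve))
  expect_equal(st$dr2s[1, 1, 1, 6], 10, tolerance = 1e-9)
  expect_equal(st$dr2s[1, 1, 1, 7], log(2) / 0.0345, tolerance = 1e-9)
})

test_that("non-positive signal flags voxels instead of zeroing them", {
  sig <- array(1000, c(2, 1, 1, 10))
  sig[1, 1, 1, 7] <- -5
  st <- compute_delta_r2star(dsc_series(sig, 0.0345, 1.02, baseline_idx = 1:3))
  expect_false(st$valid[1, 1, 1])
  expect_true(st$valid[2, 1, 1])
  expect_true(all(is.na(st$dr2s[1, 1, 1, ])))
})

test_that("trapezoidal CBV matches hand and Gamma-function oracles", {
  # constant 10 1/s over 10 intervals at dt = 1.02 -> 102
  st <- compute_delta_r2star(make_series(rep(0, 15)))
  st$dr2s[] <- 10
  m <- integrate_cbv(st, window = 1:11)
  expect_equal(m$cbv[1, 1, 1], 102, tolerance = 1e-9)

  # all-zero curve -> 0
  st0 <- compute_delta_r2star(make_series(rep(0, 15)))
  expect_equal(max(abs(integrate_cbv(st0, window = 6:15)$cbv)), 0)

  # gamma-variate area vs closed form amp * beta^(a+1) * Gamma(a+1), < 1%
  dt <- 0.25
  t <- seq(0, 120, by = dt)
  for (p in list(c(3, 3, 0.8), c(2.5, 4, 1.2))) {
    cv <- gamma_variate(t, t0 = 5, alpha = p[1], beta = p[2], amp = p[3])
    sig <- array(rep(1000 * exp(-0.0345 * cv), each = 1),
                 c(1, 1, 1, length(t)))
    st <- compute_delta_r2star(dsc_series(sig, 0.0345, dt, baseline_idx = 1:10))
    got <- integrate_cbv(st, window = seq_along(t))$cbv[1, 1, 1]
    expect_rel_error(got, gamma_variate_area(p[1], p[2], p[3]), 0.01)
  }

  expect_error(integrate_cbv(st0, window = 5L), "2 samples")
})

test_that("integration is linear in the curve", {
  st <- compute_delta_r2star(make_series(c(rep(0, 5), 1, 3, 2, 0.5, 0)))
  a <- integrate_cbv(st, window = 5:10)$cbv
  st2 <- st; st2$dr2s <- 2.5 * st$dr2s
  expect_equal(integrate_cbv(st2, window = 5:10)$cbv, 2.5 * a,
               tolerance = 1e-12)
})

test_that("relative CBV is the ratio of ROI means with validity handling", {
  cbv <- array(1, c(4, 4, 1))
  cbv[1:2, , ] <- 0.65
  map <- structure(list(cbv = cbv, valid = array(TRUE, dim(cbv)),
                        spacing_mm = c(1, 1, 1)), class = "cbv_map")
  tum <- array(FALSE, dim(cbv)); tum[1:2, , ] <- TRUE
  con <- array(FALSE, dim(cbv)); con[3:4, , ] <- TRUE
  rois <- roi_set(tum, con)
  expect_equal(relative_cbv(map, rois)$rcbv, 0.65, tolerance = 1e-15)

  # identical values -> 1; positive rescaling leaves the ratio unchanged
  map1 <- map; map1$cbv[] <- 3.3
  expect_equal(relative_cbv(map1, rois)$rcbv, 1.0)
  map2 <- map; map2$cbv <- 7.7 * map$cbv
  expect_equal(relative_cbv(map2, rois)$rcbv, 0.65, tolerance = 1e-15)

  # zero contralateral -> error
  map3 <- map; map3$cbv[3:4, , ] <- 0
  expect_error(relative_cbv(map3, rois), "zero")

  # <50% valid voxels -> error
  map4 <- map; map4$valid[1:2, , ] <- FALSE
  expect_error(relative_cbv(map4, rois), "50%")
})

test_that("Bonferroni threshold is alpha / n", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 64 * 64 * 5), 0.05 / 20480)
  expect_lt(abs(bonferroni_threshold(0.05, 20480) - 2.441e-6), 1e-9)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("display normalization is an affine min-max rescale", {
  x <- array(c(2, 4, 6), c(3, 1, 1))
  expect_equal(as.vector(normalize_map(x)), c(0, 0.5, 1))
  expect_error(normalize_map(array(5, c(3, 1, 1))), "constant")
  # invariance under positive affine pre-transforms
  set.seed(12)
  y <- array(runif(27), c(3, 3, 3))
  expect_equal(normalize_map(3.2 * y + 11), normalize_map(y),
               tolerance = 1e-12)
})

test_that("the whole pipeline is invariant to signal scaling", {
  sim <- gen_dsc(dsc_sim_spec(rcbv_ratio = 0.8, noise_sd = 0, seed = 2))
  r1 <- relative_cbv(integrate_cbv(compute_delta_r2star(sim$series)),
                     sim$rois)
  ser2 <- sim$series
  ser2$signal <- 4.2 * ser2$signal
  r2 <- relative_cbv(integrate_cbv(compute_delta_r2star(ser2)), sim$rois)
  expect_equal(r2$rcbv, r1$rcbv, tolerance = 1e-12)
})

test_that("noise-free end-to-end recovery is exact to 1e-10", {
  for (ratio in c(0.65, 1.26, 1.13)) {
    sim <- gen_dsc(dsc_sim_spec(rcbv_ratio = ratio, noise_sd = 0, seed = 1))
    res <- relative_cbv(integrate_cbv(compute_delta_r2star(sim$series)),
                        sim$rois)
    expect_rel_error(res$rcbv, ratio, 1e-10)
  }
})
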