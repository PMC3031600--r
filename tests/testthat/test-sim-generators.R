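# Synthetic-data generator contracts: determinism, stated degenerate cases,
# ground-truth consistency.

test_that("all generators are bit-identical under a fixed seed", {
  t1 <- gen_tree(tree_spec(domain_edge_mm = 1, target_density = 20, seed = 4))
  t2 <- gen_tree(tree_spec(domain_edge_mm = 1, target_density = 20, seed = 4))
  expect_identical(t1, t2)

  d1 <- gen_dsc(dsc_sim_spec(noise_sd = 12, seed = 5))
  d2 <- gen_dsc(dsc_sim_spec(noise_sd = 12, seed = 5))
  expect_identical(d1, d2)

  i1 <- gen_ihc(ihc_sim_spec(px_um = 1, seed = 6))
  i2 <- gen_ihc(ihc_sim_spec(px_um = 1, seed = 6))
  expect_identical(i1, i2)

  g1 <- gen_growth(growth_sim_spec(cv = 0.15, seed = 7))
  g2 <- gen_growth(growth_sim_spec(cv = 0.15, seed = 7))
  expect_identical(g1, g2)
})

test_that("generators leave the caller RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_growth(growth_sim_spec(cv = 0.2, seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("tree truth hits the rounded density target", {
  # density 74.29 in a 1 mm^3 domain -> exactly 74 daughters (segment
  # lengths shortened so the packing fits the small domain)
  tr <- gen_tree(tree_spec(domain_edge_mm = 1, target_density = 74.29,
                           seg_length_mean_mm = 0.22,
                           seg_length_min_mm = 0.15, seed = 2))
  expect_true(tr$truth$n_daughters %in% c(74L, 75L))
  expect_lt(abs(tr$truth$density_per_mm3 - 74.29) / 74.29, 0.02)
  # every daughter has a recorded parent, planted angle and length
  segs <- tr$truth$segments
  dtr <- segs[!is.na(segs$parent), ]
  expect_true(all(is.finite(dtr$angle_deg)))
  expect_true(all(dtr$length_mm > 0))
})

test_that("degenerate zero-variance angles are planted exactly", {
  # collinear growth forms a straight chain, so keep the count low enough
  # to fit along the domain
  tr <- gen_tree(tree_spec(domain_edge_mm = 1.5, target_density = 8 / 3.375,
                           seg_length_mean_mm = 0.22,
                           seg_length_min_mm = 0.15,
                           angle_mean_deg = 0, angle_sd_deg = 0,
                           clearance_mm = 0, seed = 3))
  ang <- tr$truth$segments$angle_deg
  expect_true(all(ang[!is.na(ang)] == 0))
})

test_that("unreachable tube packing fails loudly", {
  expect_error(gen_tree(tree_spec(domain_edge_mm = 1, target_density = 500,
                                  radius_mm = 0.1, voxel_mm = 0.05,
                                  seed = 1)),
               "unreachable|packing")
})

test_that("rasterized tubes stay inside the volume and cover the truth", {
  tr <- gen_tree(tree_spec(domain_edge_mm = 1, target_density = 15, seed = 8))
  vox <- tr$volume$voxels
  # no foreground on the boundary faces (tubes fit inside the domain)
  expect_false(any(vox[1, , ], vox[dim(vox)[1], , ], vox[, 1, ],
                   vox[, dim(vox)[2], ], vox[, , 1], vox[, , dim(vox)[3]]))
  # every truth segment midpoint rasterizes to foreground
  segs <- tr$truth$segments
  mid <- cbind((segs$x1 + segs$x2) / 2, (segs$y1 + segs$y2) / 2,
               (segs$z1 + segs$z2) / 2)
  ijk <- matrix(pmax(1, round(mid / tr$volume$voxel_mm + 0.5)), ncol = 3)
  hits <- vapply(seq_len(nrow(ijk)),
                 function(r) vox[ijk[r, 1], ijk[r, 2], ijk[r, 3]],
                 logical(1))
  expect_true(all(hits))
})

test_that("rasterize-then-measure length agrees with planted length", {
  # single straight tube: skeleton length vs truth, allowing the expected
  # cap erosion of ~1 tube radius at each free end plus one voxel diagonal
  truth <- structure(list(
    segments = data.frame(id = 1L, parent = NA_integer_,
                          x1 = 0.2, y1 = 0.5, z1 = 0.5,
                          x2 = 1.8, y2 = 0.6, z2 = 0.55,
                          length_mm = sqrt(1.6^2 + 0.1^2 + 0.05^2),
                          angle_deg = NA_real_),
    domain_edge_mm = 2, voxel_mm = 0.04519, radius_mm = 0.05,
    n_daughters = 0L, density_per_mm3 = 0), class = "vessel_tree_truth")
  vol <- rasterize_tree(truth)
  g <- extract_graph(skeletonize_3d(vol))
  expect_equal(nrow(g$segments), 1L)
  tol <- 2 * truth$radius_mm + sqrt(3) * truth$voxel_mm
  expect_lt(abs(g$segments$length_mm - truth$segments$length_mm), tol)
})

test_that("DSC generator satisfies its symmetry and scaling contracts", {
  # ratio 1, no noise: tumor and contralateral series identical
  sim <- gen_dsc(dsc_sim_spec(rcbv_ratio = 1, noise_sd = 0, seed = 1))
  sig <- sim$series$signal
  d <- dim(sig)
  m <- matrix(sig, prod(d[1:3]), d[4])
  tum <- m[as.vector(sim$rois$tumor_mask), , drop = FALSE]
  con <- m[as.vector(sim$rois$contralateral_mask), , drop = FALSE]
  expect_equal(colMeans(tum), colMeans(con), tolerance = 1e-12)

  # amp 0, no noise: flat series at s0
  flat <- gen_dsc(dsc_sim_spec(bolus_amp = 0, noise_sd = 0, s0 = 777, seed = 1))
  expect_equal(range(flat$series$signal), c(777, 777))

  # baseline mean approximately s0 under noise
  noisy <- gen_dsc(dsc_sim_spec(noise_sd = 10, s0 = 1000, seed = 3))
  bl <- noisy$series$signal[, , , noisy$series$baseline_idx]
  expect_lt(abs(mean(bl) - 1000), 2)

  # ROIs disjoint, truth ratio passed through
  expect_false(any(sim$rois$tumor_mask & sim$rois$contralateral_mask))
  expect_equal(sim$truth_ratio, 1)

  # integrated area is linear in bolus amplitude (noise-free)
  area_of <- function(amp) {
    s <- gen_dsc(dsc_sim_spec(bolus_amp = amp, noise_sd = 0, seed = 1))
    m <- integrate_cbv(compute_delta_r2star(s$series))
    mean(m$cbv[s$rois$contralateral_mask])
  }
  expect_equal(area_of(1.0), 2 * area_of(0.5), tolerance = 1e-9)

  # catastrophic noise -> explicit failure
  expect_error(gen_dsc(dsc_sim_spec(noise_sd = 600, seed = 1)),
               "noise_sd too large")
})

test_that("IHC generator plants analytic areas and degenerate fields", {
  blank <- gen_ihc(ihc_sim_spec(n_vessels = 0, px_um = 1, noise_sd = 0,
                                seed = 1))
  expect_equal(nrow(blank$truth), 0L)
  expect_equal(length(unique(as.vector(blank$field$image))), 1L)

  # a single circle of radius 2.5 um: truth area is pi * 2.5^2
  one <- gen_ihc(ihc_sim_spec(n_vessels = 1, area_mean_um2 = pi * 2.5^2,
                              area_sd_um2 = 0, px_um = 0.5, seed = 2))
  expect_equal(one$truth$area_um2, pi * 2.5^2, tolerance = 1e-9)

  # sample mean of planted areas approaches the target over many fields
  areas <- unlist(lapply(1:20, function(s) {
    gen_ihc(ihc_sim_spec(area_mean_um2 = 16.45, area_sd_um2 = 6,
                         px_um = 1, seed = s))$truth$area_um2
  }))
  expect_rel_error(mean(areas), 16.45, 0.1)

  # impossible packing fails loudly
  expect_error(gen_ihc(ihc_sim_spec(field_um = 40, px_um = 1, n_vessels = 50,
                                    area_mean_um2 = 100, seed = 1)),
               "could not place")
})
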