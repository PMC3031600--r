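# Morphometry on constructed phantoms and generator ground truth.

test_that("skeletonization contracts hold on phantoms", {
  expect_error(skeletonize_3d(binary_volume(array(FALSE, c(4, 4, 4)), 0.05)),
               "empty")

  # straight tube -> single 26-connected path with exactly 2 endpoints
  arr <- tube_array(c(50, 11, 11), c(5, 6, 6), c(45, 6, 6), 2)
  sk <- skeletonize_3d(binary_volume(arr, 0.05))
  expect_equal(skeleton_components(sk), 1L)
  se <- vasculomorph:::skeleton_edges(sk$voxels)
  g <- igraph::make_empty_graph(n = length(se$idx), directed = FALSE)
  g <- igraph::add_edges(g, t(se$edges))
  deg <- igraph::degree(g)
  expect_equal(sum(deg == 1), 2L)       # two curve endpoints
  expect_true(all(deg <= 2))            # one voxel wide, no junctions

  # two disjoint tubes -> two skeleton components
  arr2 <- arr
  arr2 <- arr2 | tube_array(c(50, 11, 11), c(5, 6, 6) + c(0, 0, 0), c(5, 6, 6), 2)
  two <- tube_array(c(40, 21, 11), c(5, 5, 6), c(35, 5, 6), 1.6) |
    tube_array(c(40, 21, 11), c(5, 15, 6), c(35, 15, 6), 1.6)
  sk2 <- skeletonize_3d(binary_volume(two, 0.05))
  expect_equal(skeleton_components(sk2), 2L)
})

test_that("skeletonization is idempotent", {
  vol <- y_phantom(50)
  sk1 <- skeletonize_3d(vol)
  sk2 <- skeletonize_3d(binary_volume(sk1$voxels, vol$voxel_mm))
  expect_identical(sk1$voxels, sk2$voxels)
})

test_that("Y phantom yields the expected graph structure", {
  g <- extract_graph(skeletonize_3d(y_phantom(45)))
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind %in% c("endpoint", "root")), 3L)
  expect_equal(nrow(g$segments), 3L)
  expect_equal(sum(!is.na(g$segments$parent)), 2L)
})

test_that("branching angles recover planted phantom angles", {
  for (ang in c(0, 45, 90)) {
    vol <- bend_phantom(ang)
    g <- extract_graph(skeletonize_3d(vol))
    segs <- g$segments
    if (ang == 0) {
      # collinear daughter: degenerates to a single straight segment
      expect_equal(nrow(segs), 1L)
      next
    }
    # daughters at the T junction measure ~0 (the continuing trunk) and
    # ~ang (the planted daughter)
    got <- segs$angle_deg[!is.na(segs$parent)]
    got <- got[is.finite(got)]
    expect_true(any(abs(got - ang) < 6),
                info = sprintf("angle %d, got %s", ang,
                               paste(round(got, 1), collapse = ",")))
  }
  # Y phantom at 45: both daughters near 45 degrees
  g <- extract_graph(skeletonize_3d(y_phantom(45)))
  got <- g$segments$angle_deg[!is.na(g$segments$parent)]
  expect_equal(length(got), 2L)
  expect_true(all(abs(got - 45) < 6))
})

test_that("tortuosity is angle over length with exclusions", {
  expect_equal(as.numeric(tortuosity(90, 2)), 45)
  expect_equal(as.numeric(tortuosity(0, 0.37)), 0)
  tau <- tortuosity(c(90, 10), c(2, 0))
  expect_equal(as.numeric(tau), 45)
  expect_equal(attr(tau, "excluded"), 1L)
  # halving lengths doubles every tortuosity value
  set.seed(5)
  ang <- runif(20, 0, 120); len <- runif(20, 0.1, 0.5)
  expect_equal(as.numeric(tortuosity(ang, len / 2)),
               2 * as.numeric(tortuosity(ang, len)), tolerance = 1e-12)
})

test_that("vessel density counts daughters by proximal node in VOI", {
  vol <- y_phantom(45)
  g <- extract_graph(skeletonize_3d(vol))
  edge <- dim(vol$voxels)[1] * vol$voxel_mm
  full <- voi("box", center_mm = rep(edge / 2, 3), size_mm = edge)
  ms <- vessel_density(g, full)
  expect_equal(ms$n_branches, 2L)
  expect_equal(ms$density_per_mm3, 2 / full$volume_mm3)
  # a VOI away from the junction holds no branch origins
  off <- voi("box", center_mm = c(edge - 0.1, edge - 0.1, edge - 0.1),
             size_mm = 0.1)
  expect_equal(vessel_density(g, off)$n_branches, 0L)
  expect_equal(vessel_density(g, off)$density_per_mm3, 0)
})

test_that("graph extraction recovers generator segment counts", {
  tr <- gen_tree(tree_spec(domain_edge_mm = 1.2, target_density = 30,
                           seed = 11))
  ms <- measure_tree(tr)
  expect_rel_error(ms$n_branches, tr$truth$n_daughters, 0.12)
  # histogram counts sum to branch count minus exclusions
  expect_equal(sum(ms$histogram$count),
               length(ms$tortuosity_deg_per_mm))
})

test_that("density recovery is monotone across generator densities", {
  meas <- vapply(c(20, 40, 80), function(dens) {
    mean(vapply(1:3, function(s) {
      measure_tree(gen_tree(tree_spec(domain_edge_mm = 1, target_density = dens,
                                      seg_length_mean_mm = 0.22,
                                      seg_length_min_mm = 0.15,
                                      seed = s)))$density_per_mm3
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})

test_that("measured angles recover a planted 45-degree tree", {
  # sparse tree: at dense packings, junction clusters occasionally merge
  # neighboring branch points and mix generations (see methods vignette)
  got <- unlist(lapply(c(13, 21), function(seed) {
    tr <- gen_tree(tree_spec(domain_edge_mm = 1.2, target_density = 8,
                             angle_mean_deg = 45, angle_sd_deg = 0,
                             seed = seed))
    g <- extract_graph(skeletonize_3d(tr$volume), root_mm = c(0, 0.6, 0.6))
    a <- g$segments$angle_deg[!is.na(g$segments$parent)]
    a[is.finite(a)]
  }))
  expect_gt(length(got), 10)
  expect_lt(abs(mean(got) - 45), 5)
})

test_that("morphometry is robust to 90-degree volume rotation", {
  vol <- y_phantom(40, leg = 30, radius = 2)
  g1 <- extract_graph(skeletonize_3d(vol))
  rot <- binary_volume(aperm(vol$voxels[, , dim(vol$voxels)[3]:1],
                             c(1, 3, 2)), vol$voxel_mm)
  g2 <- extract_graph(skeletonize_3d(rot))
  a1 <- sort(g1$segments$angle_deg[!is.na(g1$segments$parent)])
  a2 <- sort(g2$segments$angle_deg[!is.na(g2$segments$parent)])
  expect_equal(length(a1), length(a2))
  expect_true(all(abs(a1 - a2) < 3))
  l1 <- sort(g1$segments$length_mm); l2 <- sort(g2$segments$length_mm)
  expect_true(all(abs(l1 - l2) / l1 < 0.05))
})

test_that("group comparison separates saline-like from dexamethasone-like trees", {
  # small but complete two-group comparison through the full pipeline
  mk <- function(edge, dens, ang, len, lmin, seeds) {
    lapply(seeds, function(s) {
      measure_tree(gen_tree(tree_spec(domain_edge_mm = edge,
                                      target_density = dens,
                                      angle_mean_deg = ang,
                                      seg_length_mean_mm = len,
                                      seg_length_min_mm = lmin,
                                      seed = s)))
    })
  }
  saline <- mk(0.9, 74.29, 70, 0.18, 0.15, 1:3)
  dex <- mk(1.2, 41.32, 40, 0.28, 0.22, 4:6)
  cmp <- compare_morphometry(saline, dex)
  expect_lt(cmp$density_p, 0.01)
  expect_lt(cmp$tortuosity_p, 0.01)
  expect_gt(cmp$density_mean_a, cmp$density_mean_b)
  expect_gt(cmp$tortuosity_mean_a, cmp$tortuosity_mean_b)
})
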