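# Constructed phantoms and small helpers shared across the suite.

# axis-aligned digital tube: radius r voxels around a straight centerline
tube_array <- function(dim, from, to, radius) {
  arr <- array(FALSE, dim)
  co <- arrayInd(seq_len(prod(dim)), dim)
  # point-segment distance in voxel units
  v <- to - from
  w <- sweep(co, 2, from, "-")
  tt <- pmin(pmax((w %*% v) / sum(v^2), 0), 1)
  d2 <- rowSums((w - tt %*% t(v))^2)
  arr[d2 <= radius^2] <- TRUE
  arr
}

# T-phantom: straight parent along +x passing through a junction at its
# midpoint, plus a daughter leaving the junction at `angle` degrees (xy
# plane). An angle of 0 degenerates to a plain straight tube (the daughter
# lies inside the parent).
bend_phantom <- function(angle_deg, leg = 20L, radius = 1.5) {
  n <- as.integer(2 * leg + 12)
  c0 <- c(5, n / 3, n / 2)
  j <- c0 + c(leg, 0, 0)
  e <- c0 + c(2 * leg, 0, 0)
  th <- angle_deg * pi / 180
  tip <- j + leg * c(cos(th), sin(th), 0)
  arr <- tube_array(c(n, n, n), c0, e, radius) |
    tube_array(c(n, n, n), j, tip, radius)
  binary_volume(arr, 0.05)
}

# Y phantom: parent along +x (longest leg, so the root lands on its free
# end), two daughters at +/- angle in the xy plane
y_phantom <- function(angle_deg = 45, leg = 18L, radius = 1.5,
                      voxel_mm = 0.05) {
  trunk <- round(1.6 * leg)
  n <- as.integer(trunk + leg + 14)
  c0 <- c(5, n / 2, n / 2)
  j <- c0 + c(trunk, 0, 0)
  th <- angle_deg * pi / 180
  t1 <- j + leg * c(cos(th), sin(th), 0)
  t2 <- j + leg * c(cos(th), -sin(th), 0)
  arr <- tube_array(c(n, n, n), c0, j, radius) |
    tube_array(c(n, n, n), j, t1, radius) |
    tube_array(c(n, n, n), j, t2, radius)
  binary_volume(arr, voxel_mm)
}

skeleton_components <- function(sk) {
  se <- vasculomorph:::skeleton_edges(sk$voxels)
  g <- igraph::make_empty_graph(n = length(se$idx), directed = FALSE)
  if (nrow(se$edges)) g <- igraph::add_edges(g, t(se$edges))
  igraph::components(g)$no
}

expect_rel_error <- function(measured, truth, tol) {
  expect_lt(abs(measured - truth) / abs(truth), tol)
}
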