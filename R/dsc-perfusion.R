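# DSC-MRI perfusion quantification: signal -> Delta-R2* -> CBV (area under
# the curve) -> tumor-to-contralateral relative CBV.  The agent is assumed
# intravascular (iron-oxide class), so the area is integrated over the full
# post-baseline acquisition with no leakage or recirculation correction.

#' Construct a DSC signal series
#'
#' @param signal 4D numeric array (x, y, z, t) of magnitude signal.
#' @param te_s echo time (s).
#' @param dt_s temporal spacing (s).
#' @param baseline_idx inclusive indices of pre-bolus timepoints used to
#'   estimate the baseline signal S0 (default: first 10).
#' @return object of class `dsc_series`.
#' @export
dsc_series <- function(signal, te_s, dt_s, baseline_idx = 1:10) {
  stop_if(length(dim(signal)) != 4L, "'signal' must be a 4D array (x,y,z,t)")
  check_positive_scalar(te_s, "te_s")
  check_positive_scalar(dt_s, "dt_s")
  baseline_idx <- as.integer(baseline_idx)
  stop_if(length(baseline_idx) == 0L, "baseline window is empty")
  stop_if(min(baseline_idx) < 1L || max(baseline_idx) > dim(signal)[4],
          "baseline_idx outside the acquired timepoints")
  structure(list(signal = signal, te_s = te_s, dt_s = dt_s,
                 baseline_idx = baseline_idx),
            class = "dsc_series")
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dsc_series> %dx%dx%d voxels, %d timepoints, TE = %g ms, dt = %g s\n",
              d[1], d[2], d[3], d[4], 1000 * x$te_s, x$dt_s))
  invisible(x)
}

#' Construct a tumor / contralateral ROI pair
#'
#' @param tumor_mask,contralateral_mask logical 3D arrays on the map grid;
#'   disjoint and each non-empty.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(tumor_mask, contralateral_mask) {
  stop_if(!identical(dim(tumor_mask), dim(contralateral_mask)),
          "masks must share a grid")
  stop_if(!any(tumor_mask) || !any(contralateral_mask),
          "each ROI must be non-empty")
  stop_if(any(tumor_mask & contralateral_mask), "ROIs must be disjoint")
  structure(list(tumor_mask = tumor_mask,
                 contralateral_mask = contralateral_mask),
            class = "roi_set")
}

#' Convert a DSC signal series to Delta-R2* curves
#'
#' Per voxel and timepoint, `DeltaR2*(t) = -log(S(t)/S0) / TE` with S0 the
#' mean signal over the baseline window. Voxels with non-positive S0 or any
#' non-positive S(t) are flagged invalid (their curves are NA), never
#' silently zeroed.
#'
#' @param series a [dsc_series()].
#' @return object of class `r2star_stack`: list with 4D array `dr2s` (1/s),
#'   `dt_s`, and logical 3D `valid`.
#' @export
compute_delta_r2star <- function(series) {
  stop_if(!inherits(series, "dsc_series"), "'series' must be a dsc_series")
  sig <- series$signal
  d <- dim(sig)
  s0 <- apply(sig[, , , series$baseline_idx, drop = FALSE], 1:3, mean)
  valid <- s0 > 0 & apply(sig > 0, 1:3, all)
  stop_if(!any(valid), "no voxel has positive baseline and signal")
  dr2s <- array(NA_real_, d)
  ok <- which(valid)
  # work in voxel-major layout: flatten space, loop over time
  sig_m <- matrix(sig, nrow = prod(d[1:3]), ncol = d[4])
  out_m <- matrix(NA_real_, nrow = prod(d[1:3]), ncol = d[4])
  out_m[ok, ] <- -log(sig_m[ok, , drop = FALSE] / s0[ok]) / series$te_s
  dr2s <- array(out_m, d)
  structure(list(dr2s = dr2s, dt_s = series$dt_s, valid = valid,
                 baseline_idx = series$baseline_idx),
            class = "r2star_stack")
}

#' Integrate Delta-R2* curves into a CBV map
#'
#' Per-voxel trapezoidal integral over `window` (default: first
#' post-baseline timepoint through the end of acquisition). Negative lobes
#' are retained; the result is proportional to blood volume in arbitrary
#' units of 1/s x s.
#'
#' @param curves an `r2star_stack` from [compute_delta_r2star()].
#' @param window integer index range to integrate over (>= 2 samples).
#' @param spacing_mm voxel spacing carried to the map (default 1).
#' @return object of class `cbv_map`: list with 3D `cbv`, `valid`,
#'   `spacing_mm`.
#' @export
integrate_cbv <- function(curves, window = NULL, spacing_mm = c(1, 1, 1)) {
  stop_if(!inherits(curves, "r2star_stack"), "'curves' must be an r2star_stack")
  d <- dim(curves$dr2s)
  if (is.null(window)) window <- (max(curves$baseline_idx) + 1L):d[4]
  window <- as.integer(window)
  stop_if(length(window) < 2L, "integration window needs at least 2 samples")
  stop_if(min(window) < 1L || max(window) > d[4], "window outside series")
  m <- matrix(curves$dr2s, nrow = prod(d[1:3]), ncol = d[4])[, window, drop = FALSE]
  # trapezoid: dt * (sum - half the endpoints)
  cbv <- curves$dt_s * (rowSums(m) - 0.5 * (m[, 1] + m[, ncol(m)]))
  structure(list(cbv = array(cbv, d[1:3]), valid = curves$valid,
                 spacing_mm = spacing_mm),
            class = "cbv_map")
}

#' Tumor-to-contralateral relative CBV
#'
#' Mean CBV over the tumor mask divided by mean CBV over the contralateral
#' mask. Invalid voxels (flagged upstream) are excluded; each ROI must
#' retain at least 50% valid voxels.
#'
#' @param map a `cbv_map`.
#' @param rois a [roi_set()] on the same grid.
#' @return list with `rcbv`, `tumor_mean`, `contralateral_mean`.
#' @export
relative_cbv <- function(map, rois) {
  stop_if(!inherits(map, "cbv_map"), "'map' must be a cbv_map")
  stop_if(!inherits(rois, "roi_set"), "'rois' must be a roi_set")
  stop_if(!identical(dim(map$cbv), dim(rois$tumor_mask)),
          "ROI grid does not match map grid")
  roi_mean <- function(mask, label) {
    ok <- mask & map$valid
    stop_if(sum(ok) < 0.5 * sum(mask),
            "fewer than 50%% of %s ROI voxels are valid", label)
    mean(map$cbv[ok])
  }
  tm <- roi_mean(rois$tumor_mask, "tumor")
  cm <- roi_mean(rois$contralateral_mask, "contralateral")
  stop_if(cm == 0, "contralateral mean CBV is zero; ratio undefined")
  list(rcbv = tm / cm, tumor_mean = tm, contralateral_mean = cm)
}

#' Bonferroni-corrected p-value threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_tests number of voxelwise tests (>= 1).
#' @return per-test threshold `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 64 * 64 * 5)  # 2.441e-06
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stop_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
          "'alpha' must be in (0, 1)")
  stop_if(!is.numeric(n_tests) || n_tests < 1, "'n_tests' must be >= 1")
  alpha / n_tests
}

#' Min-max normalize a map for display
#'
#' Affine rescale of in-mask values to [0, 1]; out-of-mask voxels are NA.
#'
#' @param map a `cbv_map` or numeric array.
#' @param mask logical array (default: all voxels / valid voxels).
#' @return numeric array in [0, 1] with NA outside the mask.
#' @export
normalize_map <- function(map, mask = NULL) {
  x <- if (inherits(map, "cbv_map")) map$cbv else map
  if (is.null(mask)) {
    mask <- if (inherits(map, "cbv_map")) map$valid else array(TRUE, dim(x))
  }
  stop_if(!any(mask), "mask is empty")
  v <- x[mask]
  rng <- range(v)
  stop_if(diff(rng) == 0, "map is constant within the mask; rescale undefined")
  out <- array(NA_real_, dim(x))
  out[mask] <- (v - rng[1]) / diff(rng)
  out
}
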