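# Synthetic immunostain fields: non-overlapping elliptical vessel
# cross-sections with lognormal areas on a darker background, emulating an
# endothelial-marker photomicrograph (0.26 mm^2 field at 20x by default).

#' IHC field simulation spec
#'
#' @param field_um field width/height in micrometers (default 510, i.e. a
#'   0.26 mm^2 square field).
#' @param px_um pixel size in micrometers.
#' @param n_vessels number of vessel cross-sections to place.
#' @param area_mean_um2,area_sd_um2 mean and SD of the per-object lognormal
#'   area distribution (µm^2).
#' @param fg,bg foreground (stain) and background mean intensities.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed RNG seed.
#' @return object of class `ihc_sim_spec`.
#' @export
ihc_sim_spec <- function(field_um = 510, px_um = 0.5, n_vessels = 20,
                         area_mean_um2 = 22.8, area_sd_um2 = 9,
                         fg = 200, bg = 40, noise_sd = 5, seed = 1L) {
  check_positive_scalar(field_um, "field_um")
  check_positive_scalar(px_um, "px_um")
  stop_if(n_vessels < 0, "'n_vessels' must be >= 0")
  check_positive_scalar(area_mean_um2, "area_mean_um2")
  check_nonneg_scalar(area_sd_um2, "area_sd_um2")
  stop_if(area_mean_um2 <= (2 * px_um)^2,
          "mean object area must exceed (2*px_um)^2 to be resolvable")
  structure(list(field_um = field_um, px_um = px_um,
                 n_vessels = as.integer(n_vessels),
                 area_mean_um2 = area_mean_um2, area_sd_um2 = area_sd_um2,
                 fg = fg, bg = bg, noise_sd = noise_sd, seed = seed),
            class = "ihc_sim_spec")
}

# lognormal(meanlog, sdlog) matching a target mean and sd
lnorm_params <- function(m, s) {
  if (s == 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic stained field with known vessel ground truth
#'
#' Objects are ellipses of random orientation and mild eccentricity whose
#' analytic areas follow the requested lognormal distribution; centers are
#' rejection-sampled so that objects never overlap (bounding-circle test
#' with a 2-pixel margin). Pixels whose centers fall inside an ellipse take
#' the foreground intensity.
#'
#' @param spec an [ihc_sim_spec()].
#' @return list with `field` (a [stain_field()]) and `truth`
#'   (data.frame: x_um, y_um, a_um, b_um, theta, area_um2).
#' @export
gen_ihc <- function(spec) {
  stop_if(!inherits(spec, "ihc_sim_spec"), "'spec' must be an ihc_sim_spec")
  n_px <- round(spec$field_um / spec$px_um)
  with_seed(spec$seed, {
    n <- spec$n_vessels
    truth <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        a_um = numeric(0), b_um = numeric(0),
                        theta = numeric(0), area_um2 = numeric(0))
    if (n > 0) {
      lp <- lnorm_params(spec$area_mean_um2, spec$area_sd_um2)
      areas <- rlnorm(n, lp$meanlog, lp$sdlog)
      ecc <- runif(n, 1, 1.5)
      a <- sqrt(areas / pi) * sqrt(ecc)   # semi-major (µm)
      b <- sqrt(areas / pi) / sqrt(ecc)   # semi-minor (µm)
      theta <- runif(n, 0, pi)
      ord <- order(-a)                     # place big objects first
      xs <- ys <- numeric(n)
      margin <- 2 * spec$px_um
      for (j in ord) {
        placed <- FALSE
        for (try in 1:500) {
          x <- runif(1, a[j] + margin, spec$field_um - a[j] - margin)
          y <- runif(1, a[j] + margin, spec$field_um - a[j] - margin)
          prev <- ord[seq_len(match(j, ord) - 1)]
          if (length(prev) == 0 ||
              all(sqrt((xs[prev] - x)^2 + (ys[prev] - y)^2) >
                  a[prev] + a[j] + margin)) {
            xs[j] <- x; ys[j] <- y; placed <- TRUE; break
          }
        }
        stop_if(!placed,
                "could not place %d non-overlapping vessels in the field", n)
      }
      truth <- data.frame(x_um = xs, y_um = ys, a_um = a, b_um = b,
                          theta = theta, area_um2 = pi * a * b)
    }
    img <- matrix(spec$bg, n_px, n_px)
    if (n > 0) {
      # pixel centers in µm
      cx <- (seq_len(n_px) - 0.5) * spec$px_um
      for (j in seq_len(n)) {
        half <- truth$a_um[j] + spec$px_um
        ix <- which(cx >= truth$x_um[j] - half & cx <= truth$x_um[j] + half)
        iy <- which(cx >= truth$y_um[j] - half & cx <= truth$y_um[j] + half)
        if (!length(ix) || !length(iy)) next
        dx <- outer(cx[ix] - truth$x_um[j], rep(1, length(iy)))
        dy <- outer(rep(1, length(ix)), cx[iy] - truth$y_um[j])
        ct <- cos(truth$theta[j]); st <- sin(truth$theta[j])
        u <- dx * ct + dy * st
        v <- -dx * st + dy * ct
        inside <- (u / truth$a_um[j])^2 + (v / truth$b_um[j])^2 <= 1
        block <- img[ix, iy]
        block[inside] <- spec$fg
        img[ix, iy] <- block
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), n_px, n_px)
    }
    list(field = stain_field(img, px_um = spec$px_um), truth = truth)
  })
}
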