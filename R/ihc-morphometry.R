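# IHC morphometry: Otsu segmentation of the stain channel, connected
# components, per-object cross-sectional areas in µm^2, and the unpaired
# t-test group comparison on pooled object areas.

#' Construct a stained-field image
#'
#' @param image numeric matrix (single stain channel) or 3D array
#'   (rows x cols x channels) with `channel` naming the stain channel.
#' @param px_um pixel size (µm).
#' @param channel stain channel index for multi-channel images.
#' @param field_id,group optional labels carried through summaries.
#' @return object of class `stain_field`.
#' @export
stain_field <- function(image, px_um, channel = 1L, field_id = NA_character_,
                        group = NA_character_) {
  check_positive_scalar(px_um, "px_um")
  if (length(dim(image)) == 3L) image <- image[, , channel]
  stop_if(!is.matrix(image), "'image' must be a matrix or 3D array")
  structure(list(image = image, px_um = px_um, field_id = field_id,
                 group = group),
            class = "stain_field")
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the image.
#'
#' @param x numeric vector or matrix of intensities (non-constant).
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale; pixels `> threshold` are
#'   foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  stop_if(diff(rng) == 0, "constant image: threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Label 8-connected foreground components
#'
#' @param fg logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(fg) {
  stop_if(!is.logical(fg) || !is.matrix(fg), "'fg' must be a logical matrix")
  idx <- which(fg)
  lab <- matrix(0L, nrow(fg), ncol(fg))
  if (!length(idx)) return(lab)
  nr <- nrow(fg)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pos <- match(idx, idx)
  key <- integer(nrow(fg) * ncol(fg))
  key[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(fg)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- key[nb] > 0L
    edges <- rbind(edges, cbind(seq_along(idx)[ok][hit], key[nb][hit]))
  }
  g <- igraph::graph_from_edgelist(rbind(edges,
                                         cbind(seq_along(idx), seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment vessel objects in a stained field
#'
#' Global Otsu threshold on the stain channel, 8-connected components, and
#' removal of components below `min_area_um2`. Border-touching objects are
#' retained but flagged.
#'
#' @param field a [stain_field()].
#' @param min_area_um2 minimum object area kept (µm^2, default 4).
#' @return list with `labels` (integer matrix, compacted labels),
#'   `threshold`, and `border` (logical per label).
#' @export
segment_vessels <- function(field, min_area_um2 = 4) {
  stop_if(!inherits(field, "stain_field"), "'field' must be a stain_field")
  thr <- otsu_threshold(field$image)
  lab <- label_components(field$image > thr)
  if (max(lab) == 0L) return(list(labels = lab, threshold = thr,
                                  border = logical(0)))
  px_area <- field$px_um^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px_area >= min_area_um2)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  border <- logical(length(keep))
  if (length(keep)) {
    edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
    border[edge_labels[edge_labels > 0L]] <- TRUE
  }
  list(labels = lab, threshold = thr, border = border)
}

#' Measure vessel count and areas in a labeled field
#'
#' @param labels integer label matrix from [segment_vessels()] (or the list
#'   it returns).
#' @param px_um pixel size (µm).
#' @return object of class `field_summary`: `n_vessels`, `areas_um2`,
#'   `mean_area_um2` (NA for an empty field).
#' @export
measure_fields <- function(labels, px_um) {
  if (is.list(labels)) labels <- labels$labels
  check_positive_scalar(px_um, "px_um")
  n <- max(labels)
  areas <- if (n > 0L) tabulate(labels[labels > 0L], n) * px_um^2 else numeric(0)
  structure(list(n_vessels = as.integer(n), areas_um2 = areas,
                 mean_area_um2 = if (n > 0L) mean(areas) else NA_real_),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("<field_summary> %d vessels, mean area %.2f um^2\n",
              x$n_vessels,
              if (is.na(x$mean_area_um2)) NA else x$mean_area_um2))
  invisible(x)
}

#' Compare pooled vessel areas between two groups
#'
#' Two-sided unpaired t-test on per-object cross-sectional areas pooled
#' over each group's fields.
#'
#' @param group_a,group_b lists of `field_summary` objects.
#' @param var_equal pooled-variance test if TRUE (default).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_vessel_area <- function(group_a, group_b, var_equal = TRUE) {
  pool <- function(g) unlist(lapply(g, function(s) s$areas_um2))
  a <- pool(group_a); b <- pool(group_b)
  stop_if(length(a) < 2L || length(b) < 2L,
          "need at least two pooled areas per group")
  res <- unpaired_t(a, b, var_equal = var_equal)
  c(res, list(mean_a = mean(a), mean_b = mean(b)))
}
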