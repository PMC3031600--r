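# File I/O.  The environment provides no R NIfTI or TIFF bindings, so a
# minimal NIfTI-1 reader/writer is implemented here (348-byte fixed header +
# raw voxel data; gzip handled by R connections) and 2D stained fields use
# plain-text PGM (P2).  Both cover exactly what the pipeline needs:
# single-file .nii/.nii.gz, datatypes uint8/int16/int32/float32/float64,
# voxel spacing via pixdim.

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param x numeric/logical array (3D or 4D).
#' @param path output path; `.gz` suffix gzip-compresses.
#' @param spacing voxel spacing per spatial axis (mm), recycled to 3.
#' @param dt_s temporal spacing for 4D data (stored in pixdim[5]).
#' @param datatype `"float32"` (default), `"uint8"`, or `"float64"`.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), dt_s = 1,
                        datatype = c("float32", "uint8", "float64")) {
  datatype <- match.arg(datatype)
  d <- dim(x)
  stop_if(is.null(d) || !(length(d) %in% c(3L, 4L)), "need a 3D or 4D array")
  spacing <- rep(spacing, length.out = 3)
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  code <- switch(datatype, uint8 = c(2L, 8L), float32 = c(16L, 32L),
                 float64 = c(64L, 64L))
  pixdim <- c(1, spacing, if (length(d) == 4L) dt_s else 1, 1, 1, 1)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_s <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i(348); w_raw(36)
  w_s(dim8)
  w_f(c(0, 0, 0)); w_s(0); w_s(code[1]); w_s(code[2]); w_s(0)
  w_f(pixdim); w_f(352); w_f(c(1, 0)); w_s(0); w_raw(2)
  w_f(c(0, 0, 0, 0)); w_i(c(0, 0))
  desc <- charToRaw(sprintf("%-80s", "vasculomorph"))[1:80]
  writeBin(desc, con); w_raw(24)
  w_s(c(0, 1))                       # qform 0, sform 1
  w_f(rep(0, 6))                     # quaternion block unused
  w_f(c(spacing[1], 0, 0, 0)); w_f(c(0, spacing[2], 0, 0))
  w_f(c(0, 0, spacing[3], 0))
  w_raw(16)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  w_raw(4)                           # no extensions
  v <- as.vector(x)
  if (datatype == "uint8") {
    writeBin(as.integer(v), con, size = 1)
  } else {
    writeBin(as.numeric(v), con,
             size = if (datatype == "float32") 4 else 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or any single-file
#' uncompressed-layout NIfTI-1 with a supported datatype)
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return list with `data` (array), `spacing` (mm), `dt_s`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348) endian <- "big"
  r_i <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "integer", n,
                                  4, endian = endian)
  r_s <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer", n,
                                  2, endian = endian)
  r_f <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n,
                                  4, endian = endian)
  dim8 <- r_s(40, 8)
  nd <- dim8[1]
  stop_if(nd < 3 || nd > 4, "only 3D/4D NIfTI supported")
  d <- dim8[2:(1 + nd)]
  datatype <- r_s(70, 1)
  pixdim <- r_f(76, 8)
  vox_offset <- r_f(108, 1)
  scl <- r_f(112, 2)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  v <- switch(as.character(datatype),
              "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE)),
              "4" = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
              "8" = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
              "16" = readBin(con, "numeric", n, 4, endian = endian),
              "64" = readBin(con, "numeric", n, 8, endian = endian),
              stop("unsupported NIfTI datatype ", datatype, call. = FALSE))
  if (!is.na(scl[1]) && scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    v <- v * scl[1] + scl[2]
  }
  list(data = array(v, d), spacing = pixdim[2:4],
       dt_s = if (nd == 4) pixdim[5] else NA_real_)
}

#' Write a matrix as plain-text PGM (P2)
#'
#' @param img numeric matrix; values clamped to [0, maxval] and rounded.
#' @param path output path.
#' @param maxval maximum gray value.
#' @param px_um optional pixel size recorded as a comment.
#' @return invisibly, `path`.
#' @export
write_pgm <- function(img, path, maxval = 255, px_um = NULL) {
  stop_if(!is.matrix(img), "'img' must be a matrix")
  v <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  if (!is.null(px_um)) writeLines(sprintf("# px_um %.6g", px_um), con)
  writeLines(sprintf("%d %d", ncol(img), nrow(img)), con)
  writeLines(as.character(maxval), con)
  write(t(v), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM path.
#' @return list with `img` (matrix) and `px_um` (if recorded, else NA).
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  stop_if(lines[1] != "P2", "only plain (P2) PGM supported")
  px_um <- NA_real_
  body <- lines[-1]
  cm <- grepl("^#", body)
  pxl <- grep("^# px_um", body, value = TRUE)
  if (length(pxl)) px_um <- as.numeric(sub("^# px_um\\s+", "", pxl[1]))
  body <- body[!cm]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(body[-(1:2)]), "\\s+")))
  stop_if(length(vals) != dims[1] * dims[2], "corrupt PGM payload")
  list(img = matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE),
       px_um = px_um)
}

#' Write a vessel graph (or tree truth) as JSON
#'
#' @param graph a `vessel_graph` or `vessel_tree_truth`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_graph_json <- function(graph, path) {
  if (inherits(graph, "vessel_graph")) {
    payload <- list(kind = "vessel_graph", nodes = graph$nodes,
                    segments = graph$segments, voxel_mm = graph$voxel_mm)
  } else if (inherits(graph, "vessel_tree_truth")) {
    payload <- list(kind = "vessel_tree_truth", segments = graph$segments,
                    domain_edge_mm = graph$domain_edge_mm,
                    voxel_mm = graph$voxel_mm, radius_mm = graph$radius_mm)
  } else {
    stop("unsupported graph object", call. = FALSE)
  }
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON config file
#'
#' @param path JSON file whose keys mirror the simulation / analysis spec
#'   constructor arguments.
#' @return named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
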