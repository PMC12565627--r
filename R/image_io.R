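#' Load a microscopy stack and reduce it to a single 2-D plane
#'
#' Fluorescence stacks are reduced to the 2-D plane the downstream
#' quantification consumes: 4-D arrays (channel, z, y, x) have their first
#' channel summed over z (an extended-depth-of-focus style projection), 3-D
#' arrays (channel, y, x) contribute their first channel directly, and 2-D
#' arrays pass through unchanged.
#'
#' Accepted inputs are a plain (multi-page) TIFF file or an in-memory numeric
#' array. Multi-page TIFFs are interpreted as a (page, y, x) stack, i.e. pages
#' are channels; a 4-D layout can be declared through the sidecar metadata
#' field \code{shape = c(n_channels, n_z)}. Physical pixel sizes are read from
#' a sidecar JSON file \code{<path>.json} with fields \code{pixel_size_x_um}
#' and/or \code{pixel_size_y_um}.
#'
#' @param x file path to a TIFF, or a numeric array with 2 to 4 dimensions.
#' @param meta optional list overriding the sidecar metadata
#'   (\code{pixel_size_x_um}, \code{pixel_size_y_um}, \code{shape}).
#' @return A \code{cell_image}: list with \code{plane} (2-D non-negative
#'   matrix) and \code{meta} (\code{pixel_size_x_um}, \code{pixel_size_y_um},
#'   \code{source_path}).
#' @export
load_image <- function(x, meta = NULL) {
  source_path <- NA_character_
  if (is.character(x)) {
    source_path <- x
    if (!file.exists(x)) {
      stop("cannot read image file: ", x, call. = FALSE)
    }
    sidecar <- read_sidecar(x)
    if (is.null(meta)) meta <- sidecar else meta <- utils::modifyList(sidecar, meta)
    pages <- tryCatch(tiff::readTIFF(x, all = TRUE, as.is = TRUE),
                      error = function(e) stop("cannot read image file: ", x,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, drop_singleton_channels)
    if (length(pages) == 1L) {
      x <- pages[[1L]]
    } else {
      x <- aperm(simplify2array(pages), c(3L, 1L, 2L)) # (page, y, x)
      if (!is.null(meta$shape)) {
        shp <- as.integer(meta$shape)
        if (length(shp) == 2L && prod(shp) == length(pages)) {
          # pages enumerate z within channel: (channel, z, y, x)
          x <- array(x, dim = c(shp[2L], shp[1L], dim(x)[2L], dim(x)[3L]))
          x <- aperm(x, c(2L, 1L, 3L, 4L))
        }
      }
    }
  }
  if (!is.numeric(x) && !is.logical(x)) {
    stop("image input must be a file path or a numeric array", call. = FALSE)
  }
  plane <- reduce_stack(x)
  new_cell_image(plane, meta = meta, source_path = source_path)
}

#' Reduce a 2- to 4-D intensity array to a 2-D plane
#'
#' @param x numeric array; 4-D is (channel, z, y, x), 3-D is (channel, y, x).
#' @return 2-D matrix; channel 1 summed over z (4-D) or taken directly (3-D).
#' @export
reduce_stack <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  if (nd == 2L) {
    plane <- as.matrix(x)
  } else if (nd == 3L) {
    plane <- array(x[1L, , ], dim = d[2:3])
  } else if (nd == 4L) {
    ch <- array(x[1L, , , ], dim = d[2:4])
    plane <- apply(ch, c(2L, 3L), sum)
  } else {
    stop("unsupported image dimensionality: array has shape (",
         paste(d, collapse = ", "), "); expected 2, 3 or 4 dimensions",
         call. = FALSE)
  }
  if (any(plane < 0)) stop("intensity plane contains negative values", call. = FALSE)
  plane
}

new_cell_image <- function(plane, meta = NULL, source_path = NA_character_) {
  structure(list(
    plane = plane,
    meta = list(
      pixel_size_x_um = meta$pixel_size_x_um %||% NA_real_,
      pixel_size_y_um = meta$pixel_size_y_um %||% NA_real_,
      source_path = source_path
    )
  ), class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat("<cell_image> ", nrow(x$plane), "x", ncol(x$plane),
      " plane, pixel size (", x$meta$pixel_size_x_um, ", ",
      x$meta$pixel_size_y_um, ") um\n", sep = "")
  invisible(x)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

drop_singleton_channels <- function(m) {
  # readTIFF returns (y, x, ch) for multi-channel pages; keep channel 1
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Resolve the isotropic physical pixel size
#'
#' When both axis sizes are present their arithmetic mean is taken as the
#' isotropic pixel size; with only one present that value is used.
#'
#' @param meta a \code{cell_image} meta list, or any list with
#'   \code{pixel_size_x_um} / \code{pixel_size_y_um}.
#' @return pixel size in micrometres (scalar, > 0).
#' @export
resolve_pixel_size <- function(meta) {
  if (inherits(meta, "cell_image")) meta <- meta$meta
  px <- meta$pixel_size_x_um %||% NA_real_
  py <- meta$pixel_size_y_um %||% NA_real_
  vals <- c(px, py)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no physical pixel size present in metadata", call. = FALSE)
  }
  if (any(vals <= 0)) stop("pixel sizes must be strictly positive", call. = FALSE)
  mean(vals)
}

#' Load a binary cell mask and match it to an image
#'
#' Masks are single-channel rasters (PNG, 8- or 16-bit) in which white pixels
#' mark the cell region. The raster is resized to \code{target_shape} by
#' nearest-neighbour interpolation and thresholded to logical at 50% of its
#' maximum value, which is robust to 8- vs 16-bit encodings.
#'
#' @param x PNG file path or a numeric/logical matrix.
#' @param target_shape integer length-2 (rows, cols) the mask must match;
#'   \code{NULL} keeps the native shape.
#' @param fill if \code{TRUE}, treat the white pixels as a closed outline and
#'   fill its interior (row/column scan fill); by default white pixels are
#'   taken as the filled cell region itself.
#' @return logical matrix with at least one \code{TRUE} pixel.
#' @export
load_mask <- function(x, target_shape = NULL, fill = FALSE) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read mask file: ", x, call. = FALSE)
    x <- tryCatch(png::readPNG(x),
                  error = function(e) stop("cannot read mask file: ", x,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
    if (length(dim(x)) == 3L) x <- x[, , 1L]
  }
  m <- as.matrix(x)
  mx <- max(m)
  region <- if (mx > 0) m > mx / 2 else matrix(FALSE, nrow(m), ncol(m))
  if (fill) region <- fill_region(region)
  if (!is.null(target_shape)) {
    region <- resize_nn(region, target_shape)
  }
  if (!any(region)) stop("mask is empty (no white pixels)", call. = FALSE)
  region
}

#' Nearest-neighbour resize of a matrix
#'
#' Centre-aligned index mapping: target pixel (i, j) takes the source pixel
#' whose centre is nearest. Identity when source and target shapes match.
#'
#' @param m matrix.
#' @param target_shape integer length-2 (rows, cols).
#' @return matrix of the requested shape.
#' @export
resize_nn <- function(m, target_shape) {
  nr <- nrow(m); nc <- ncol(m)
  tr <- as.integer(target_shape[1L]); tc <- as.integer(target_shape[2L])
  if (tr == nr && tc == nc) return(m)
  ri <- pmin(pmax(ceiling((seq_len(tr) - 0.5) * nr / tr), 1L), nr)
  ci <- pmin(pmax(ceiling((seq_len(tc) - 0.5) * nc / tc), 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Fill the interior of a closed outline: a pixel is interior when rays along
# all four axis directions hit outline pixels. Adequate for convex manual
# contours; provided because an outline has near-zero area and would corrupt
# the area normalisation.
fill_region <- function(outline) {
  up <- apply(outline, 2L, cummax)
  down <- apply(outline[rev(seq_len(nrow(outline))), , drop = FALSE], 2L, cummax)
  down <- down[rev(seq_len(nrow(outline))), , drop = FALSE]
  left <- t(apply(outline, 1L, cummax))
  right <- t(apply(outline[, rev(seq_len(ncol(outline))), drop = FALSE], 1L, cummax))
  right <- right[, rev(seq_len(ncol(outline))), drop = FALSE]
  (up & down & left & right) | outline
}

`%||%` <- function(a, b) if (is.null(a)) b else a
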