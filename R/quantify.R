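#' Projected cell area from a binary mask
#'
#' The number of in-mask pixels multiplied by the squared isotropic pixel
#' size, i.e. the 2-D projected area in square micrometres. Area normalises
#' all downstream intensity readouts so that lysosomal/mitochondrial content
#' is compared per cytoplasmic territory rather than per cell.
#'
#' @param mask logical matrix, \code{TRUE} inside the cell.
#' @param pixel_size isotropic pixel size in micrometres (> 0).
#' @return area in square micrometres.
#' @export
projected_area <- function(mask, pixel_size) {
  n <- sum(mask)
  if (n == 0L) stop("mask is empty (no white pixels)", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be strictly positive", call. = FALSE)
  }
  n * pixel_size^2
}

#' Per-pixel intensity densities within a mask
#'
#' Every raw fluorescence value inside the mask divided by the cell's
#' projected area, yielding intensity densities in arbitrary units per square
#' micrometre. One value per in-mask pixel; feeds the distributional
#' (lysosomal) arm of the analysis.
#'
#' @param image a \code{cell_image} or a 2-D matrix.
#' @param mask logical matrix of the same shape.
#' @param area projected area in square micrometres (> 0).
#' @return numeric vector, length = number of \code{TRUE} mask pixels.
#' @export
pixel_densities <- function(image, mask, area) {
  plane <- if (inherits(image, "cell_image")) image$plane else image
  if (!all(dim(plane) == dim(mask))) {
    stop("image and mask shapes differ: (",
         paste(dim(plane), collapse = "x"), ") vs (",
         paste(dim(mask), collapse = "x"), ")", call. = FALSE)
  }
  if (area <= 0) stop("area must be strictly positive", call. = FALSE)
  plane[mask] / area
}

#' Mean intensity density of a cell
#'
#' Integrated in-mask fluorescence divided by the projected area: one scalar
#' per cell (a.u. per square micrometre), independent of cell morphology.
#' Feeds the mitochondrial membrane-potential arm.
#'
#' @inheritParams pixel_densities
#' @return scalar mean density.
#' @export
mean_density <- function(image, mask, area) {
  plane <- if (inherits(image, "cell_image")) image$plane else image
  if (!all(dim(plane) == dim(mask))) {
    stop("image and mask shapes differ: (",
         paste(dim(plane), collapse = "x"), ") vs (",
         paste(dim(mask), collapse = "x"), ")", call. = FALSE)
  }
  if (area <= 0) stop("area must be strictly positive", call. = FALSE)
  sum(plane[mask]) / area
}

#' Nuclear-to-cytoplasmic enrichment ratio
#'
#' Mean intensity over the nuclear mask divided by the mean over the
#' cytoplasmic mask (enrichment = mean nucleus intensity / mean cytoplasm
#' intensity); the p16 partitioning readout. Masks must be disjoint.
#'
#' @param image a \code{cell_image} or 2-D matrix.
#' @param nuclear_mask,cytoplasm_mask disjoint non-empty logical matrices.
#' @return dimensionless ratio (>= 0).
#' @export
nc_enrichment <- function(image, nuclear_mask, cytoplasm_mask) {
  plane <- if (inherits(image, "cell_image")) image$plane else image
  if (!any(nuclear_mask) || !any(cytoplasm_mask)) {
    stop("nuclear and cytoplasmic masks must both be non-empty", call. = FALSE)
  }
  if (any(nuclear_mask & cytoplasm_mask)) {
    stop("nuclear and cytoplasmic masks overlap", call. = FALSE)
  }
  cyt <- mean(plane[cytoplasm_mask])
  if (cyt == 0) {
    stop("cytoplasmic mean intensity is zero; enrichment ratio undefined",
         call. = FALSE)
  }
  mean(plane[nuclear_mask]) / cyt
}

#' Quantify all cells listed in a manifest
#'
#' Runs the image -> mask -> area -> density chain for every row of a
#' manifest. Condition labels come from the manifest, never from filename
#' parsing.
#'
#' @param manifest data.frame (or CSV path) with columns \code{image_path},
#'   \code{mask_path}, \code{donor}, \code{inducer}, \code{cell_id}.
#' @return data.frame with one row per cell: \code{cell_id}, \code{donor},
#'   \code{inducer}, \code{area_um2}, \code{n_pixels}, \code{mean_density},
#'   plus a \code{densities} list-column of per-pixel densities.
#' @export
quantify_cells <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("image_path", "mask_path", "donor", "inducer", "cell_id")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  per_cell <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_image(manifest$image_path[i])
    mask <- load_mask(manifest$mask_path[i], target_shape = dim(img$plane))
    area <- projected_area(mask, resolve_pixel_size(img))
    list(row = data.frame(cell_id = manifest$cell_id[i],
                          donor = manifest$donor[i],
                          inducer = manifest$inducer[i],
                          area_um2 = area,
                          n_pixels = sum(mask),
                          mean_density = mean_density(img, mask, area),
                          stringsAsFactors = FALSE),
         densities = pixel_densities(img, mask, area))
  })
  out <- do.call(rbind, lapply(per_cell, `[[`, "row"))
  out$densities <- lapply(per_cell, `[[`, "densities")
  out
}
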