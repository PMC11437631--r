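#' Binary vessel raster mask
#'
#' Wraps a binary matrix holding the segmentation of one vessel class
#' (artery or vein). Any nonzero entry is foreground. Coordinates
#' throughout the package are 1-based \code{(row, col)} pixel positions;
#' node positions may be continuous (cluster centroids).
#'
#' @param grid numeric/logical/integer matrix; nonzero = vessel.
#' @param vessel_class \code{"artery"} or \code{"vein"}.
#' @param pixel_size scalar pixel scale (default 1; lengths are in px).
#' @return An object of class \code{raster_mask}: list with elements
#'   \code{grid} (logical matrix), \code{vessel_class}, \code{pixel_size}.
#' @export
raster_mask <- function(grid, vessel_class = c("artery", "vein"),
                        pixel_size = 1) {
  vessel_class <- match.arg(vessel_class)
  if (!is.matrix(grid)) stop("grid must be a matrix")
  g <- grid != 0
  g[is.na(g)] <- FALSE
  structure(list(grid = g, vessel_class = vessel_class,
                 pixel_size = pixel_size),
            class = "raster_mask")
}

#' @export
print.raster_mask <- function(x, ...) {
  cat(sprintf("<raster_mask> %s, %d x %d px, %d foreground px\n",
              x$vessel_class, nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Optic-disc geometry
#'
#' Disc center and diameter define the measurement annulus (0.5 to 2.0
#' disc diameters outward from the disc edge) and the vertex of the main
#' angle.
#'
#' @param center numeric length-2, (row, col) in px.
#' @param diameter disc diameter D in px, > 0.
#' @return Object of class \code{disc_geometry}.
#' @export
disc_geometry <- function(center, diameter) {
  center <- as.numeric(center)
  if (length(center) != 2 || any(!is.finite(center)))
    stop("center must be a finite (row, col) pair")
  if (!is.numeric(diameter) || length(diameter) != 1 || diameter <= 0)
    stop("diameter must be a positive scalar")
  structure(list(center = center, diameter = diameter),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf("<disc_geometry> center (%.1f, %.1f), D = %.1f px\n",
              x$center[1], x$center[2], x$diameter))
  invisible(x)
}

#' Read a vessel mask from a PNG or TIFF file
#'
#' Any nonzero pixel (any channel) is treated as foreground.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @inheritParams raster_mask
#' @return A \code{raster_mask}.
#' @export
read_vessel_mask <- function(path, vessel_class = c("artery", "vein")) {
  vessel_class <- match.arg(vessel_class)
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext)
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  raster_mask(img != 0, vessel_class = vessel_class)
}

#' Write a mask as an 8-bit PNG (0 background, 255 vessel)
#'
#' @param mask a \code{raster_mask}.
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
write_vessel_mask <- function(mask, path) {
  stopifnot(inherits(mask, "raster_mask"))
  png::writePNG(mask$grid * 1.0, target = path)
  invisible(path)
}

#' Read a disc annotation JSON
#'
#' Expected schema: \code{{"center": [row, col], "diameter": D}}.
#'
#' @param path JSON file path.
#' @return A \code{disc_geometry}.
#' @export
read_disc_annotation <- function(path) {
  if (!file.exists(path)) stop("disc annotation not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$center) || is.null(j$diameter))
    stop("disc JSON must contain 'center' and 'diameter'")
  disc_geometry(j$center, j$diameter)
}

#' Write a disc annotation JSON
#' @param disc a \code{disc_geometry}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_disc_annotation <- function(disc, path) {
  stopifnot(inherits(disc, "disc_geometry"))
  jsonlite::write_json(list(center = disc$center, diameter = disc$diameter),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
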