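#' Categorical LULC map on a regular grid
#'
#' The central raster container: an integer matrix of class codes plus its
#' legend and grid metadata. The nodata code is fixed at 0 internally; any
#' other nodata convention is remapped on read.
#'
#' @param values integer matrix of class codes (0 = nodata). Rows run from the
#'   top of the map downwards, columns left to right.
#' @param legend a [lulc_legend()].
#' @param cell_size cell edge length in metres (default 60, the analysis
#'   resolution).
#' @param origin numeric length-2, (x, y) of the lower-left corner in metres.
#' @param crs opaque CRS tag (free text, compared verbatim).
#' @return An object of class `lulc_map`.
#' @export
lulc_map <- function(values, legend, cell_size = 60, origin = c(0, 0), crs = "") {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (cell_size <= 0) stop("cell_size must be > 0")
  bad <- !(values %in% c(0L, legend$code))
  if (any(bad))
    stop(sum(bad), " cell(s) carry codes outside the legend; remap before construction")
  structure(list(values = values, legend = legend, cell_size = cell_size,
                 origin = as.numeric(origin), crs = as.character(crs),
                 nodata = 0L),
            class = "lulc_map")
}

#' @export
print.lulc_map <- function(x, ...) {
  cat("<lulc_map> ", nrow(x$values), "x", ncol(x$values),
      " cells @ ", x$cell_size, " m, ", nrow(x$legend), " classes, ",
      sum(x$values == 0L), " nodata\n", sep = "")
  invisible(x)
}

#' @export
dim.lulc_map <- function(x) dim(x$values)

#' Continuous or categorical driver layer
#'
#' @param name driver name.
#' @param values numeric matrix, same shape as the companion map.
#' @param kind `"static"` or `"dynamic"`. Dynamic layers are re-derivable from
#'   the evolving cover map during a simulation and must carry a `recompute`
#'   rule.
#' @param categorical logical; `TRUE` when values are class codes.
#' @param recompute for dynamic layers, a list naming the recomputation rule,
#'   e.g. `list(fun = "distance_to_class", class_code = 5L)`.
#' @return An object of class `driver_layer`.
#' @export
driver_layer <- function(name, values, kind = c("static", "dynamic"),
                         categorical = FALSE, recompute = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("values must be a matrix")
  if (kind == "dynamic" && is.null(recompute))
    stop("dynamic driver layers must declare a recompute rule")
  structure(list(name = name, values = values, kind = kind,
                 categorical = categorical, recompute = recompute),
            class = "driver_layer")
}

#' Boolean mask layer
#' @param name mask name.
#' @param values logical matrix.
#' @return An object of class `mask_layer`.
#' @export
mask_layer <- function(name, values) {
  if (!is.matrix(values) || !is.logical(values))
    stop("values must be a logical matrix")
  structure(list(name = name, values = values), class = "mask_layer")
}

# Grid conformity: shape always; cell size + origin to 1e-6 m when both sides
# carry them; CRS text compared verbatim, mismatch is a warning only.
check_conform <- function(a, b, what = "layer") {
  va <- if (is.matrix(a)) a else a$values
  vb <- if (is.matrix(b)) b else b$values
  if (!identical(dim(va), dim(vb)))
    stop(what, " grid shape ", paste(dim(vb), collapse = "x"),
         " does not conform to ", paste(dim(va), collapse = "x"))
  if (inherits(a, "lulc_map") && inherits(b, "lulc_map")) {
    if (abs(a$cell_size - b$cell_size) > 1e-6)
      stop("cell size mismatch: ", a$cell_size, " vs ", b$cell_size)
    if (any(abs(a$origin - b$origin) > 1e-6))
      stop("grid origin mismatch")
    if (!identical(a$crs, b$crs))
      warning("CRS tags differ ('", a$crs, "' vs '", b$crs, "'); proceeding")
  }
  invisible(TRUE)
}

valid_cells <- function(map) map$values != map$nodata

#' Per-class areas of a map
#' @param map an `lulc_map`.
#' @return An [area_vector()] of per-class areas in hectares.
#' @param year calendar year to attach (default `NA`).
#' @export
class_areas <- function(map, year = NA_integer_) {
  cell_ha <- map$cell_size^2 / 1e4
  counts <- tabulate(map$values[valid_cells(map)], nbins = max(map$legend$code))
  area_vector(counts[map$legend$code] * cell_ha, map$legend, year = year)
}
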