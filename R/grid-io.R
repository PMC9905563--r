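#' Read a categorical LULC raster
#'
#' Reads a single-band integer raster in ESRI ASCII grid format (`.asc`) and
#' binds it to a legend. Cells whose code is not in the legend are set to
#' nodata and counted in a warning; input nodata is remapped to the internal
#' nodata code 0.
#'
#' @param path path to an ASCII grid file.
#' @param legend a [lulc_legend()].
#' @param crs optional CRS tag to attach (the format itself carries none).
#' @return An [lulc_map()].
#' @export
read_categorical <- function(path, legend, crs = "") {
  g <- read_ascii_grid(path)
  v <- g$values
  v[is.na(v)] <- 0
  storage.mode(v) <- "integer"
  unknown <- v != 0L & !(v %in% legend$code)
  if (any(unknown)) {
    warning(sum(unknown), " cell(s) with codes outside the legend set to nodata")
    v[unknown] <- 0L
  }
  if (all(v == 0L)) stop("degenerate input: all cells are nodata")
  lulc_map(v, legend, cell_size = g$cell_size, origin = g$origin, crs = crs)
}

#' Write a categorical LULC raster
#' @param map an `lulc_map`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_categorical <- function(map, path) {
  v <- map$values
  v[v == 0L] <- NA
  write_ascii_grid(v, path, cell_size = map$cell_size, origin = map$origin,
                   nodata = -9999)
}

#' Read a continuous driver raster
#' @param path `.asc` path.
#' @param name driver name (default: file base name).
#' @param kind `"static"` or `"dynamic"`.
#' @param categorical logical.
#' @param recompute recompute rule for dynamic layers.
#' @return A [driver_layer()].
#' @export
read_driver <- function(path, name = tools::file_path_sans_ext(basename(path)),
                        kind = "static", categorical = FALSE, recompute = NULL) {
  g <- read_ascii_grid(path)
  driver_layer(name, g$values, kind = kind, categorical = categorical,
               recompute = recompute)
}

#' Write a driver raster
#' @param driver a `driver_layer`.
#' @param path output `.asc` path.
#' @param cell_size,origin grid metadata to stamp on the file.
#' @return `path`, invisibly.
#' @export
write_driver <- function(driver, path, cell_size = 60, origin = c(0, 0)) {
  write_ascii_grid(driver$values, path, cell_size = cell_size, origin = origin,
                   nodata = -9999)
}

#' Read a mask raster (nonzero = TRUE)
#' @param path `.asc` path.
#' @param name mask name.
#' @return A [mask_layer()].
#' @export
read_mask <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  g <- read_ascii_grid(path)
  v <- g$values
  v[is.na(v)] <- 0
  mask_layer(name, v != 0)
}

#' Write a mask raster (TRUE = 1, FALSE = 0)
#' @param mask a `mask_layer`.
#' @param path output `.asc` path.
#' @param cell_size,origin grid metadata.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, cell_size = 60, origin = c(0, 0)) {
  write_ascii_grid(mask$values * 1L, path, cell_size = cell_size,
                   origin = origin, nodata = -9999)
}

# ESRI ASCII grid: a 6-line header (ncols, nrows, xllcorner, yllcorner,
# cellsize, NODATA_value) followed by nrows whitespace-separated rows, top
# row first. No R raster package is available in this stack, so the format
# is handled directly; it round-trips integer codes bit-exactly.
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(0); vals <- list()
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  h <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated ASCII grid: ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (tolower(parts[1]) %in% keys) {
      h[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      vals[[length(vals) + 1]] <- as.numeric(parts)
      break
    }
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(h[[k]])) stop("ASCII grid header missing ", k)
  rest <- scan(con, what = numeric(), quiet = TRUE)
  flat <- c(unlist(vals), rest)
  nr <- as.integer(h$nrows); nc <- as.integer(h$ncols)
  if (length(flat) != nr * nc)
    stop("ASCII grid body has ", length(flat), " values, expected ", nr * nc)
  m <- matrix(flat, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(h$nodata_value)) m[m == h$nodata_value] <- NA
  list(values = m, cell_size = h$cellsize,
       origin = c(h$xllcorner %||% 0, h$yllcorner %||% 0))
}

write_ascii_grid <- function(values, path, cell_size, origin = c(0, 0),
                             nodata = -9999) {
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a categorical map to a new cell size
#'
#' Nearest-neighbour by default (each target cell takes the code of the source
#' cell containing its centre); an optional majority filter takes the modal
#' code of the source cells whose centres fall in each target cell (sensible
#' when coarsening).
#'
#' @param map an `lulc_map`.
#' @param target_cell target cell size in metres.
#' @param method `"nearest"` (default) or `"majority"`.
#' @return An `lulc_map` on the new grid; the legend is preserved.
#' @export
resample_to_grid <- function(map, target_cell, method = c("nearest", "majority")) {
  method <- match.arg(method)
  if (target_cell <= 0) stop("target_cell must be > 0")
  if (abs(target_cell - map$cell_size) < 1e-12) return(map)
  nr <- nrow(map$values); nc <- ncol(map$values)
  new_nr <- max(1L, as.integer(round(nr * map$cell_size / target_cell)))
  new_nc <- max(1L, as.integer(round(nc * map$cell_size / target_cell)))
  if (method == "nearest") {
    # source row/col containing each target cell centre
    ri <- pmin(nr, pmax(1L, ceiling(((seq_len(new_nr) - 0.5) * target_cell) / map$cell_size)))
    ci <- pmin(nc, pmax(1L, ceiling(((seq_len(new_nc) - 0.5) * target_cell) / map$cell_size)))
    v <- map$values[ri, ci, drop = FALSE]
  } else {
    # target cell of each source cell centre; modal code per target cell
    tr <- pmin(new_nr, pmax(1L, ceiling(((seq_len(nr) - 0.5) * map$cell_size) / target_cell)))
    tc <- pmin(new_nc, pmax(1L, ceiling(((seq_len(nc) - 0.5) * map$cell_size) / target_cell)))
    idx <- (rep(tc, each = nr) - 1L) * new_nr + rep(tr, nc)
    v <- matrix(0L, new_nr, new_nc)
    agg <- tapply(as.vector(map$values), idx, function(z) {
      z <- z[z != 0L]
      if (!length(z)) return(0L)
      as.integer(names(which.max(table(z))))
    })
    v[as.integer(names(agg))] <- as.integer(agg)
  }
  lulc_map(v, map$legend, cell_size = target_cell, origin = map$origin,
           crs = map$crs)
}

#' Rasterize polygons to a mask on a map's grid
#'
#' A cell is TRUE iff its centre lies inside any polygon (even-odd rule).
#'
#' @param polygons a two-column coordinate matrix (one ring), or a list of
#'   such matrices. Rings need not be closed.
#' @param grid an `lulc_map` defining the target grid.
#' @param name mask name.
#' @return A [mask_layer()].
#' @export
rasterize_mask <- function(polygons, grid, name = "mask") {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (length(polygons) == 0) {
    warning("empty geometry set: all-false mask")
    return(mask_layer(name, matrix(FALSE, nr, nc)))
  }
  cs <- grid$cell_size
  xs <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  ys <- grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs  # row 1 = top
  pts <- cbind(rep(xs, each = nr), rep(ys, nc))
  inside <- rep(FALSE, nrow(pts))
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3) stop("polygon rings need at least 3 vertices")
    inside <- inside | mgcv::in.out(rbind(poly, poly[1, ]), pts)
  }
  mask_layer(name, matrix(inside, nr, nc))
}
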