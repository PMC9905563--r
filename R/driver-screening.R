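#' Euclidean distance to the nearest cell of a class
#'
#' Exact Euclidean distance between cell centres, in metres; zero on cells of
#' the class itself. The layer is marked dynamic (it is re-derivable from the
#' evolving cover map during a simulation).
#'
#' @param map an `lulc_map`.
#' @param class_code legend code of the target class.
#' @return A [driver_layer()] named `"distance_to_<class>"`.
#' @export
distance_to_class <- function(map, class_code) {
  if (!class_code %in% map$legend$code) stop("class ", class_code, " not in legend")
  name <- paste0("distance_to_", gsub("\\s+", "_", legend_name(map$legend, class_code)))
  rec <- list(fun = "distance_to_class", class_code = as.integer(class_code))
  if (!any(map$values == class_code)) {
    warning("class ", class_code, " absent from map: all distances infinite")
    return(driver_layer(name, matrix(Inf, nrow(map$values), ncol(map$values)),
                        kind = "dynamic", recompute = rec))
  }
  fg <- (map$values != class_code) * 1  # background (0) = target class
  d <- EBImage::distmap(fg, metric = "euclidean") * map$cell_size
  driver_layer(name, matrix(as.numeric(d), nrow(fg)), kind = "dynamic",
               recompute = rec)
}

# Connected-component labels of cells of one class on the grid.
label_patches <- function(values, class_code, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(values); nc <- ncol(values)
  on <- which(values == class_code)
  if (!length(on)) return(list(labels = matrix(0L, nr, nc), sizes = integer(0)))
  id <- integer(nr * nc)
  id[on] <- seq_along(on)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  r <- ((on - 1L) %% nr) + 1L
  cc <- ((on - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[nb] > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(id[on[ok]][hit], id[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  labels <- matrix(0L, nr, nc)
  labels[on] <- comp$membership
  list(labels = labels, sizes = comp$csize)
}

#' Patch-size map for a class
#'
#' Every cell of `class_code` holds the area (ha) of the connected patch it
#' belongs to; all other cells are 0.
#'
#' @param map an `lulc_map`.
#' @param class_code legend code.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return A [driver_layer()] named `"patch_size_<class>"`, marked dynamic.
#' @export
patch_size_map <- function(map, class_code, connectivity = 8) {
  if (!class_code %in% map$legend$code) stop("class ", class_code, " not in legend")
  lp <- label_patches(map$values, class_code, connectivity)
  cell_ha <- map$cell_size^2 / 1e4
  v <- matrix(0, nrow(map$values), ncol(map$values))
  if (length(lp$sizes)) {
    on <- lp$labels > 0L
    v[on] <- lp$sizes[lp$labels[on]] * cell_ha
  }
  driver_layer(paste0("patch_size_", gsub("\\s+", "_", legend_name(map$legend, class_code))),
               v, kind = "dynamic",
               recompute = list(fun = "patch_size_map",
                                class_code = as.integer(class_code),
                                connectivity = connectivity))
}

#' Cramer's V association between a driver and the class map
#'
#' Continuous drivers are binned into `n_bins` equal-width classes over their
#' observed range; categorical drivers use their codes directly. V is
#' computed from the bin-by-class contingency table as
#' `sqrt(chi2 / (N * (min(r, c) - 1)))` after dropping empty rows/columns;
#' nodata cells and non-finite driver values are excluded.
#'
#' @param driver a `driver_layer`.
#' @param map the companion `lulc_map`.
#' @param n_bins number of equal-width bins for continuous drivers
#'   (default 256).
#' @param threshold selection threshold on V (default 0.15).
#' @return A one-row data frame of class `association_result`:
#'   `driver`, `v`, `n_bins`, `selected`.
#' @export
cramers_v <- function(driver, map, n_bins = 256, threshold = 0.15) {
  check_conform(map, driver, "driver")
  keep <- valid_cells(map) & is.finite(driver$values)
  x <- driver$values[keep]
  y <- map$values[keep]
  if (!length(x)) stop("no jointly valid cells")
  if (length(unique(x)) < 2) {
    warning("driver '", driver$name, "' is constant: V = 0")
    v <- 0
  } else {
    if (driver$categorical) {
      xf <- factor(x)
    } else {
      if (n_bins < 2) stop("n_bins must be >= 2 for continuous drivers")
      brk <- seq(min(x), max(x), length.out = n_bins + 1)
      xf <- cut(x, breaks = brk, include.lowest = TRUE)
    }
    tab <- table(xf, factor(y))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (min(dim(tab)) < 2) {
      v <- 0
    } else {
      chi2 <- suppressWarnings(
        as.numeric(stats::chisq.test(tab, correct = FALSE)$statistic))
      v <- sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1)))
      v <- min(1, max(0, v))
    }
  }
  structure(data.frame(driver = driver$name, v = v,
                       n_bins = if (driver$categorical) NA_integer_ else as.integer(n_bins),
                       selected = v >= threshold, stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Screen a set of drivers by Cramer's V
#'
#' @param results a data frame of association results (rows from
#'   [cramers_v()], e.g. `do.call(rbind, ...)`).
#' @param threshold selection threshold (default 0.15).
#' @return The selected rows, `selected = TRUE`, sorted by V descending.
#' @export
select_drivers <- function(results, threshold = 0.15) {
  out <- results[results$v >= threshold, , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  out <- out[order(-out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen many drivers against a map in one call
#' @param drivers list of `driver_layer`s.
#' @param map companion `lulc_map`.
#' @param n_bins,threshold passed to [cramers_v()].
#' @return Data frame with one association row per driver (all drivers, with
#'   their `selected` flags; see [select_drivers()] to filter).
#' @export
screen_drivers <- function(drivers, map, n_bins = 256, threshold = 0.15) {
  do.call(rbind, lapply(drivers, cramers_v, map = map, n_bins = n_bins,
                        threshold = threshold))
}
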