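#' Cross-tabulate two dated LULC maps
#'
#' Counts, for every ordered class pair (i, j), the cells that were class i at
#' the earlier date and class j at the later date. Cells that are nodata at
#' either date are excluded.
#'
#' @param map_t0,map_t1 `lulc_map`s on the same grid with the same legend.
#' @param interval_years length of the observation interval in years.
#' @return An object of class `crosstab`: list with `counts` (K x K integer
#'   matrix, rows = earlier date, cols = later date, dimnames = class names),
#'   `cell_area_ha`, `legend`, `interval_years`.
#' @export
cross_tabulate <- function(map_t0, map_t1, interval_years = 1) {
  check_conform(map_t0, map_t1, "map")
  if (!same_legend(map_t0$legend, map_t1$legend)) stop("legends differ")
  if (interval_years <= 0) stop("interval_years must be positive")
  keep <- valid_cells(map_t0) & valid_cells(map_t1)
  codes <- map_t0$legend$code
  counts <- table(factor(map_t0$values[keep], levels = codes),
                  factor(map_t1$values[keep], levels = codes))
  counts <- matrix(as.integer(counts), nrow = length(codes),
                   dimnames = list(map_t0$legend$name, map_t0$legend$name))
  structure(list(counts = counts,
                 cell_area_ha = map_t0$cell_size^2 / 1e4,
                 legend = map_t0$legend,
                 interval_years = interval_years),
            class = "crosstab")
}

#' Build a cross-tabulation from a transition area table
#'
#' Reconstructs a `crosstab` from a published transition table (rows
#' `from`, `to`, `area_ha`): off-diagonal counts from the stated areas,
#' diagonals from stated persistence areas (or, by default, made large enough
#' that no class empties). With `cell_area_ha = 1` the stated hectare figures
#' are preserved exactly.
#'
#' @param specs data frame with columns `from`, `to`, `area_ha`.
#' @param legend the companion [lulc_legend()].
#' @param cell_area_ha area of one notional cell (ha).
#' @param persistence_ha optional vector of diagonal areas (ha), legend order.
#' @param interval_years interval covered by the table.
#' @return A `crosstab` (see [cross_tabulate()]).
#' @export
crosstab_from_table <- function(specs, legend, cell_area_ha = 0.36,
                                persistence_ha = NULL, interval_years = 14) {
  k <- nrow(legend)
  counts <- matrix(0, k, k, dimnames = list(legend$name, legend$name))
  for (i in seq_len(nrow(specs))) {
    counts[specs$from[i], specs$to[i]] <- round(specs$area_ha[i] / cell_area_ha)
  }
  if (is.null(persistence_ha))
    diag(counts) <- pmax(rowSums(counts) * 4, round(1e6 / cell_area_ha))
  else
    diag(counts) <- round(persistence_ha / cell_area_ha)
  structure(list(counts = counts, cell_area_ha = cell_area_ha,
                 legend = legend, interval_years = interval_years),
            class = "crosstab")
}

#' Select major transitions from a cross-tabulation
#'
#' Off-diagonal transitions whose area is at least `min_area_ha` are kept
#' (ties at the threshold are included: areas strictly below it are ignored)
#' and returned sorted by area descending. Submodel membership is looked up
#' in `assignment` (a data frame `from,to,submodel`); pairs without an
#' assignment get `NA`.
#'
#' @param ct a `crosstab`.
#' @param min_area_ha minimum transition area in hectares (default 5000).
#' @param assignment submodel assignment table; defaults to the packaged
#'   seven-class assignment (see [submodel_assignment()]).
#' @return A data frame of class `transition_specs` with columns
#'   `from`, `to` (class names), `submodel`, `area_ha`.
#' @export
select_transitions <- function(ct, min_area_ha = 5000,
                               assignment = NULL) {
  if (min_area_ha < 0) stop("min_area_ha must be >= 0")
  if (is.null(assignment)) assignment <- submodel_assignment()
  cn <- colnames(ct$counts)
  area <- ct$counts * ct$cell_area_ha
  diag(area) <- 0
  idx <- which(area >= min_area_ha & area > 0, arr.ind = TRUE)
  specs <- data.frame(from = cn[idx[, 1]], to = cn[idx[, 2]],
                      area_ha = area[idx], stringsAsFactors = FALSE)
  key <- paste(specs$from, specs$to, sep = " -> ")
  akey <- paste(assignment$from, assignment$to, sep = " -> ")
  specs$submodel <- assignment$submodel[match(key, akey)]
  specs <- specs[order(-specs$area_ha), c("from", "to", "submodel", "area_ha")]
  rownames(specs) <- NULL
  class(specs) <- c("transition_specs", "data.frame")
  specs
}

#' Group transitions into change submodels
#'
#' Groups selected transitions by submodel (degradation, substitution,
#' regeneration, or any user-defined grouping) with per-group totals.
#'
#' @param specs a `transition_specs` data frame (see [select_transitions()]).
#' @return A named list, one entry per submodel, each a list with `specs`
#'   (the member rows) and `total_area_ha`. Submodels named in the default
#'   assignment but absent from `specs` appear with zero totals.
#' @export
group_submodels <- function(specs) {
  levels <- c("degradation", "substitution", "regeneration")
  extra <- setdiff(unique(specs$submodel[!is.na(specs$submodel)]), levels)
  out <- lapply(c(levels, extra), function(s) {
    m <- specs[!is.na(specs$submodel) & specs$submodel == s, , drop = FALSE]
    list(specs = m, total_area_ha = sum(m$area_ha))
  })
  names(out) <- c(levels, extra)
  out
}

#' The packaged submodel assignment for the seven-class legend
#'
#' Maps each of the 14 major transitions of the 2002-2016 Colombian Amazon
#' analysis to its change submodel (degradation, substitution, regeneration).
#' Packaged as data so other regions can supply their own table.
#'
#' @return Data frame with columns `from`, `to`, `submodel`.
#' @export
submodel_assignment <- function() {
  t1 <- load_fixture("table1")
  t1[, c("from", "to", "submodel")]
}

#' Write a transition table to CSV
#' @param specs a `transition_specs` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE)
  invisible(path)
}
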