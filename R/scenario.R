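#' Assemble a complete scenario specification
#'
#' Packages a named scenario's Markov matrix, loss trajectory, constraint
#' masks (potential forced to 0 for the affected transitions) and incentive
#' masks (potential multiplied, clipped to 1) into one object:
#' * `trend`: the historical matrix as-is; an optional conservation-agreement
#'   incentive on the pastures -> fragmented recovery transition (a warning is
#'   issued when the mask is missing).
#' * `extractivist`: requires a `mining_titles` mask, applied as an incentive
#'   on the forest-loss transitions.
#' * `sustainable`: requires protection masks (`protected_areas`,
#'   `indigenous_reservations`, optionally `steep_slopes`) applied as
#'   constraints on forest-loss transitions, plus an optional `restoration`
#'   incentive on pastures -> fragmented.
#'
#' @param name `"trend"`, `"extractivist"` or `"sustainable"`.
#' @param matrix a `transition_matrix` for the scenario.
#' @param masks named list of [mask_layer()]s (see above).
#' @param trajectory optional [loss_trajectory()].
#' @param horizon_year horizon (default 2040).
#' @param incentive_multiplier multiplier for incentive masks (default 1.5).
#' @param forest_classes class names counted as forest for loss transitions;
#'   default: legend names containing "forest".
#' @param annual_steps logical: simulate year by year (default TRUE).
#' @return An object of class `scenario_spec`.
#' @export
build_scenario <- function(name = c("trend", "extractivist", "sustainable"),
                           matrix, masks = list(), trajectory = NULL,
                           horizon_year = 2040, incentive_multiplier = 1.5,
                           forest_classes = NULL, annual_steps = TRUE) {
  name <- match.arg(name)
  if (incentive_multiplier <= 0) stop("incentive multiplier must be > 0")
  leg <- matrix$legend
  if (is.null(forest_classes))
    forest_classes <- grep("forest", leg$name, value = TRUE)
  loss_tr <- forest_loss_transitions(matrix, forest_classes)
  recovery <- recovery_transition(leg)
  constraints <- list(); incentives <- list()
  need <- function(key) {
    if (is.null(masks[[key]]))
      stop("scenario '", name, "' requires mask '", key, "'")
    masks[[key]]
  }
  if (name == "trend") {
    if (is.null(masks$conservation_agreements))
      warning("no conservation_agreements mask supplied; ",
              "trend scenario runs without the recovery incentive")
    else
      incentives[[length(incentives) + 1]] <-
        list(mask = masks$conservation_agreements, transitions = recovery,
             multiplier = incentive_multiplier)
  } else if (name == "extractivist") {
    incentives[[length(incentives) + 1]] <-
      list(mask = need("mining_titles"), transitions = loss_tr,
           multiplier = incentive_multiplier)
  } else {
    prot <- list(need("protected_areas"), need("indigenous_reservations"))
    if (!is.null(masks$steep_slopes)) prot <- c(prot, list(masks$steep_slopes))
    for (mk in prot)
      constraints[[length(constraints) + 1]] <-
        list(mask = mk, transitions = loss_tr)
    if (is.null(masks$restoration))
      warning("no restoration mask supplied; ",
              "sustainable scenario runs without the restoration incentive")
    else
      incentives[[length(incentives) + 1]] <-
        list(mask = masks$restoration, transitions = recovery,
             multiplier = incentive_multiplier)
  }
  structure(list(name = name, horizon_year = horizon_year, matrix = matrix,
                 trajectory = trajectory, constraints = constraints,
                 incentives = incentives, forest_classes = forest_classes,
                 annual_steps = annual_steps),
            class = "scenario_spec")
}

# All from-forest to-non-forest transitions present in the matrix.
forest_loss_transitions <- function(matrix, forest_classes) {
  leg <- matrix$legend
  out <- list()
  for (f in forest_classes) for (t in setdiff(leg$name, forest_classes))
    if (matrix$p[f, t] > 0) out[[length(out) + 1]] <- c(from = f, to = t)
  out
}

recovery_transition <- function(legend) {
  from <- grep("pastures", legend$name, value = TRUE)
  to <- grep("fragmented", legend$name, value = TRUE)
  if (length(from) == 1 && length(to) == 1)
    list(c(from = from, to = to))
  else list()
}

transition_key <- function(from, to) {
  if (!length(from)) return(character(0))
  paste(from, "->", to)
}

spec_has_transition <- function(entry, from, to) {
  any(vapply(entry$transitions,
             function(tr) tr[["from"]] == from && tr[["to"]] == to, logical(1)))
}

#' Apply scenario constraints and incentives to a potential raster
#'
#' Incentives first (multiply, clip to 1), then constraints (set to 0), so a
#' constraint always dominates.
#'
#' @param potential a `potential_raster` whose `transition` carries the
#'   `"change: from -> to"` label, or a plain matrix plus `from`/`to`.
#' @param spec a `scenario_spec`.
#' @param from,to class names when `potential` is a plain matrix.
#' @return The modified potential (same type as supplied).
#' @export
apply_constraints_and_incentives <- function(potential, spec,
                                             from = NULL, to = NULL) {
  if (inherits(potential, "potential_raster")) {
    lab <- sub("^change: ", "", potential$transition)
    parts <- strsplit(lab, " -> ", fixed = TRUE)[[1]]
    from <- parts[1]; to <- parts[2]
    v <- potential$values
  } else v <- potential
  for (inc in spec$incentives)
    if (spec_has_transition(inc, from, to)) {
      check_conform(v, inc$mask, "incentive mask")
      v[inc$mask$values] <- pmin(1, v[inc$mask$values] * inc$multiplier)
    }
  for (con in spec$constraints)
    if (spec_has_transition(con, from, to)) {
      check_conform(v, con$mask, "constraint mask")
      v[con$mask$values] <- 0
    }
  if (inherits(potential, "potential_raster")) {
    potential$values <- v
    potential
  } else v
}

#' Slope constraint mask from a DEM
#'
#' Slope (percent) is rise/run x 100 from central differences on the grid,
#' taking the steepest of the two axis gradients and the two diagonal
#' gradients; one-sided differences at the edges. Cells strictly steeper than
#' `threshold_percent` are masked.
#'
#' @param dem a `driver_layer` of elevations in metres on the analysis grid.
#' @param threshold_percent slope threshold (default 100, i.e. 45 degrees).
#' @param cell_size grid cell size in metres (default 60).
#' @return A [mask_layer()] named `"steep_slopes"`.
#' @export
slope_constraint <- function(dem, threshold_percent = 100, cell_size = 60) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  clamp_r <- function(i) pmin(nr, pmax(1L, i))
  clamp_c <- function(i) pmin(nc, pmax(1L, i))
  cd <- function(dr, dc) {
    # central difference along (dr, dc), one-sided at edges: the physical
    # distance between the two (clamped) sample points is used as the run
    rp <- clamp_r(seq_len(nr) + dr); rm <- clamp_r(seq_len(nr) - dr)
    cp <- clamp_c(seq_len(nc) + dc); cm <- clamp_c(seq_len(nc) - dc)
    dz <- abs(z[rp, cp, drop = FALSE] - z[rm, cm, drop = FALSE])
    run <- sqrt(outer((rp - rm)^2, rep(1, nc)) +
                outer(rep(1, nr), (cp - cm)^2)) * cell_size
    out <- dz / pmax(run, .Machine$double.eps)
    out[run == 0] <- 0
    out
  }
  g <- pmax(cd(1L, 0L), cd(0L, 1L), cd(1L, 1L), cd(1L, -1L))
  mask_layer("steep_slopes", g * 100 > threshold_percent)
}
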