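#' Per-step transition demand in cells
#'
#' Applies the annualized matrix to the evolving class totals, keeping a
#' real-valued recursion for the class areas and converting each step's flows
#' to integer cell counts by largest-remainder rounding per source class, so
#' per-class outflow totals track the real-valued demand within one cell.
#'
#' @param m a `transition_matrix` (annualized internally if needed).
#' @param map_t0 the starting `lulc_map`.
#' @param steps number of steps (years for an annual matrix).
#' @param per_interval if `TRUE`, one step spans the matrix's own interval
#'   (no annualization).
#' @return A `demand_table` data frame: `step`, `from`, `to`,
#'   `cells` (off-diagonal transitions with nonzero demand only).
#' @export
demand_to_cells <- function(m, map_t0, steps, per_interval = FALSE) {
  if (!same_legend(m$legend, map_t0$legend)) stop("matrix legend does not match map")
  ann <- if (per_interval || m$interval_years == 1) m else annualize(m)
  codes <- m$legend$code
  n <- as.numeric(tabulate(map_t0$values[valid_cells(map_t0)],
                           nbins = max(codes))[codes])
  k <- length(codes)
  rows <- list()
  for (s in seq_len(steps)) {
    for (i in seq_len(k)) {
      flows <- n[i] * ann$p[i, ]
      cells <- largest_remainder(flows)
      for (j in seq_len(k)) {
        if (i != j && cells[j] > 0)
          rows[[length(rows) + 1]] <- data.frame(
            step = s, from = m$legend$name[i], to = m$legend$name[j],
            cells = cells[j])
      }
    }
    n <- as.numeric(n %*% ann$p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), from = character(0), to = character(0),
               cells = integer(0))
  class(out) <- c("demand_table", "data.frame")
  out
}

# Integer apportionment preserving the rounded total (Hamilton's method).
largest_remainder <- function(x) {
  fl <- floor(x)
  total <- round(sum(x))
  short <- total - sum(fl)
  if (short > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  as.integer(fl)
}

#' Allocate one step of demanded change by ranked potentials
#'
#' For each transition, eligible cells (current class = source class,
#' potential > 0) are claimed in descending potential until the demand is
#' met. A cell eligible for several transitions goes to the one where it
#' holds the highest potential (ties broken by a seeded uniform draw). A
#' second pass lets transitions with remaining demand take still-unchanged
#' eligible cells in descending potential, so feasible demand is not left
#' unmet by the conflict rule. Shortfalls are recorded, not raised.
#'
#' @param current the current `lulc_map`.
#' @param potentials named list of `potential_raster`s (or plain matrices),
#'   names `"from -> to"`.
#' @param demand named integer vector of cells to change per transition
#'   (same names), or a one-step `demand_table`.
#' @param seed RNG seed for tie-breaking.
#' @return List with `map` (the updated `lulc_map`) and `ledger` (data frame
#'   `from`, `to`, `demanded`, `achieved`, `unmet`).
#' @export
allocate_step <- function(current, potentials, demand, seed = 1) {
  if (is.data.frame(demand))
    demand <- stats::setNames(demand$cells, transition_key(demand$from, demand$to))
  demand <- demand[demand > 0]
  keys <- names(demand)
  v <- current$values
  ledger <- data.frame(from = character(0), to = character(0),
                       demanded = integer(0), achieved = integer(0),
                       unmet = integer(0))
  if (!length(keys))
    return(list(map = current, ledger = ledger))
  set.seed(seed)
  k <- length(keys)
  parts <- strsplit(keys, " -> ", fixed = TRUE)
  from_code <- vapply(parts, function(p) legend_code(current$legend, p[1]), integer(1))
  to_code <- vapply(parts, function(p) legend_code(current$legend, p[2]), integer(1))
  pot <- lapply(keys, function(kk) {
    p <- potentials[[kk]]
    if (is.null(p)) stop("no potential raster for transition '", kk, "'")
    if (inherits(p, "potential_raster")) p$values else p
  })
  # eligibility and per-cell best transition (argmax potential, seeded ties)
  ncell <- length(v)
  best_pot <- matrix(-Inf, nrow(v), ncol(v))
  best_tr <- matrix(0L, nrow(v), ncol(v))
  jit <- lapply(seq_len(k), function(t)
    matrix(stats::runif(ncell, 0, 1e-9), nrow(v), ncol(v)))
  for (t in seq_len(k)) {
    elig <- v == from_code[t] & !is.na(pot[[t]]) & pot[[t]] > 0
    p_t <- pot[[t]] + jit[[t]]
    take <- elig & p_t > best_pot
    best_pot[take] <- p_t[take]
    best_tr[take] <- t
  }
  achieved <- integer(k)
  changed <- matrix(FALSE, nrow(v), ncol(v))
  new_v <- v
  for (t in seq_len(k)) {
    cand <- which(best_tr == t)
    if (length(cand)) {
      ord <- cand[order(-best_pot[cand])]
      take <- ord[seq_len(min(demand[t], length(ord)))]
      new_v[take] <- to_code[t]
      changed[take] <- TRUE
      achieved[t] <- length(take)
    }
  }
  # fill pass: remaining demand takes unclaimed, still-unchanged eligible cells
  remaining <- demand - achieved
  for (t in order(-remaining)) {
    if (remaining[t] <= 0) next
    elig <- which(v == from_code[t] & !changed & !is.na(pot[[t]]) & pot[[t]] > 0)
    if (!length(elig)) next
    ord <- elig[order(-(pot[[t]][elig] + jit[[t]][elig]))]
    take <- ord[seq_len(min(remaining[t], length(ord)))]
    new_v[take] <- to_code[t]
    changed[take] <- TRUE
    achieved[t] <- achieved[t] + length(take)
  }
  out_map <- current
  out_map$values <- new_v
  ledger <- data.frame(from = vapply(parts, `[`, "", 1),
                       to = vapply(parts, `[`, "", 2),
                       demanded = as.integer(demand),
                       achieved = achieved,
                       unmet = as.integer(demand) - achieved)
  list(map = out_map, ledger = ledger)
}

#' Simulate a scenario to its horizon
#'
#' Annual loop: per-step demand is derived from the scenario's (annualized)
#' matrix applied to the evolving class totals (rescaled to the loss
#' trajectory's forest loss when one is attached), constraints and incentives
#' are applied to the transition potentials, and change is placed by
#' [allocate_step()]. Unmet demand is carried into the next step (optional).
#' Dynamic drivers are recomputed and potentials re-predicted every
#' `recalc_every` steps when a model and drivers are supplied.
#'
#' @param spec a `scenario_spec`.
#' @param map_t0 the starting `lulc_map`.
#' @param potentials named list of potential rasters, names `"from -> to"`.
#' @param start_year calendar year of `map_t0` (default 2016).
#' @param output_years years at which to keep maps (default: the horizon).
#' @param seed RNG seed (tie-breaking; deterministic under a fixed seed).
#' @param model optional `mlp_model` for re-prediction.
#' @param drivers optional list of `driver_layer`s (needed with `model`).
#' @param recalc_every recompute dynamic drivers every this many steps
#'   (default 5; 0 disables).
#' @param carry_unmet carry unmet demand forward (default TRUE).
#' @return A `simulation_result`: list with `maps` (named by year), `ledger`
#'   (per step and transition: demanded/achieved/unmet), `seed`.
#' @export
simulate_scenario <- function(spec, map_t0, potentials, start_year = 2016,
                              output_years = NULL, seed = 1, model = NULL,
                              drivers = NULL, recalc_every = 5,
                              carry_unmet = TRUE) {
  horizon <- spec$horizon_year
  if (is.null(output_years)) output_years <- horizon
  if (any(output_years > horizon)) stop("output_years beyond the horizon")
  if (isFALSE(spec$annual_steps)) {
    # one allocation step per matrix interval
    step_years <- spec$matrix$interval_years
    if ((horizon - start_year) %% step_years != 0)
      stop("horizon - start_year must be a multiple of the matrix interval")
    n_steps <- (horizon - start_year) %/% step_years
    ann <- spec$matrix
  } else {
    step_years <- 1
    n_steps <- horizon - start_year
    ann <- if (spec$matrix$interval_years == 1) spec$matrix else annualize(spec$matrix)
  }
  leg <- map_t0$legend
  cell_ha <- map_t0$cell_size^2 / 1e4
  # constraints/incentives are static masks: apply once up front
  pots <- potentials
  apply_masks <- function(pots) {
    for (kk in names(pots)) {
      parts <- strsplit(kk, " -> ", fixed = TRUE)[[1]]
      pots[[kk]] <- apply_constraints_and_incentives(
        if (inherits(pots[[kk]], "potential_raster")) pots[[kk]]$values else pots[[kk]],
        spec, from = parts[1], to = parts[2])
    }
    pots
  }
  pots <- apply_masks(pots)
  cur <- map_t0
  maps <- list()
  ledgers <- list()
  carry <- NULL
  fr_idx <- match(spec$forest_classes, leg$name)
  for (s in seq_len(n_steps)) {
    year <- start_year + s * step_years
    dem <- demand_to_cells(ann, cur, steps = 1, per_interval = TRUE)
    if (!is.null(spec$trajectory)) {
      # rescale forest-loss demand to the trajectory's loss for this year
      tl <- spec$trajectory$loss_ha[match(year, spec$trajectory$year)]
      if (!is.na(tl)) {
        is_loss <- dem$from %in% spec$forest_classes &
          !(dem$to %in% spec$forest_classes)
        cur_loss <- sum(dem$cells[is_loss]) * cell_ha
        if (cur_loss > 0) {
          fac <- tl / cur_loss
          dem$cells[is_loss] <- largest_remainder(dem$cells[is_loss] * fac)
        }
      }
    }
    dvec <- stats::setNames(dem$cells, transition_key(dem$from, dem$to))
    if (carry_unmet && length(carry)) {
      for (kk in names(carry)) {
        prev <- if (kk %in% names(dvec)) dvec[[kk]] else 0L
        dvec[kk] <- prev + carry[[kk]]
      }
    }
    dvec <- dvec[dvec > 0]
    # keep only transitions we have potentials for; others are reported unmet
    missing <- setdiff(names(dvec), names(pots))
    step_res <- allocate_step(cur, pots, dvec[setdiff(names(dvec), missing)],
                              seed = seed + s)
    cur <- step_res$map
    led <- step_res$ledger
    if (length(missing)) {
      parts <- strsplit(missing, " -> ", fixed = TRUE)
      led <- rbind(led, data.frame(
        from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
        demanded = as.integer(dvec[missing]), achieved = 0L,
        unmet = as.integer(dvec[missing])))
    }
    if (nrow(led)) led <- cbind(step = s, year = year, led)
    ledgers[[s]] <- led
    carry <- if (nrow(led)) stats::setNames(led$unmet, transition_key(led$from, led$to)) else NULL
    carry <- carry[carry > 0]
    if (!is.null(model) && !is.null(drivers) && recalc_every > 0 &&
        s %% recalc_every == 0) {
      drivers <- lapply(drivers, recompute_driver, map = cur)
      for (kk in names(pots)) {
        lab <- paste0("change: ", kk)
        if (lab %in% model$classes)
          pots[[kk]] <- predict_potential(model, drivers, lab, map = cur)$values
      }
      pots <- apply_masks(pots)
    }
    if (year %in% output_years) maps[[as.character(year)]] <- cur
  }
  structure(list(maps = maps,
                 ledger = do.call(rbind, ledgers[lengths(ledgers) > 0]),
                 seed = seed),
            class = "simulation_result")
}

recompute_driver <- function(driver, map) {
  if (driver$kind != "dynamic" || is.null(driver$recompute)) return(driver)
  rc <- driver$recompute
  out <- switch(rc$fun,
    distance_to_class = distance_to_class(map, rc$class_code),
    patch_size_map = patch_size_map(map, rc$class_code,
                                    connectivity = rc$connectivity %||% 8),
    driver)
  out$name <- driver$name
  out
}
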