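#' Configuration for a synthetic study landscape
#'
#' Defines a fully self-contained synthetic system: a spatially
#' autocorrelated initial cover map, driver layers with planted responses, and
#' a known ("true") transition matrix that links the two dated maps. Every
#' pipeline stage can then be verified by parameter recovery.
#'
#' @param grid_size `(rows, cols)`, at least 16 x 16 (default 128 x 128).
#' @param seed integer RNG seed (default 20230207).
#' @param true_matrix a `transition_matrix`; default: a 4-class
#'   forest/fragmented/pasture/water system over a 14-year interval with
#'   degradation (forest -> fragmented), substitution (fragmented -> pasture),
#'   mild regeneration (pasture -> fragmented) and inert water.
#' @param driver_spec list of driver descriptors
#'   `list(name, kind, effect_weight, class_code)` with kind one of
#'   `"distance_seeded"`, `"gradient"`, `"random_field"`. The default plants
#'   a negative response on distance-to-pasture, a positive response on an
#'   accessibility gradient, and a zero-weight noise field.
#' @param patchiness Gaussian-smoothing radius (cells) controlling spatial
#'   autocorrelation of the cover map (default 8).
#' @param priors target class proportions (default 0.55/0.20/0.20/0.05).
#' @param noise_sd jitter (potential scale) on the planted change ranking
#'   (default 0.02, small against the ~0.8 potential spread so the planted
#'   ranking stays recoverable).
#' @param cell_size cell size in metres (default 60).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_size = c(128, 128), seed = 20230207,
                             true_matrix = NULL, driver_spec = NULL,
                             patchiness = 8, priors = c(0.55, 0.20, 0.20, 0.05),
                             noise_sd = 0.02, cell_size = 60) {
  if (any(grid_size < 16)) stop("grid_size must be at least 16 x 16")
  if (is.null(true_matrix)) {
    leg <- synthetic_legend()
    p <- rbind(c(0.90, 0.08, 0.02, 0.00),
               c(0.02, 0.88, 0.10, 0.00),
               c(0.00, 0.05, 0.95, 0.00),
               c(0.00, 0.00, 0.00, 1.00))
    true_matrix <- transition_matrix(p, interval_years = 14, leg)
  }
  if (is.null(driver_spec))
    driver_spec <- list(
      list(name = "dist_pastures", kind = "distance_seeded",
           effect_weight = -2.5, class_code = 3L),
      list(name = "accessibility", kind = "gradient", effect_weight = 1.5),
      list(name = "noise_field", kind = "random_field", effect_weight = 0))
  if (length(priors) != nrow(true_matrix$legend))
    stop("priors must match the legend")
  priors <- priors / sum(priors)
  structure(list(grid_size = as.integer(grid_size), seed = as.integer(seed),
                 true_matrix = true_matrix, driver_spec = driver_spec,
                 patchiness = patchiness, priors = priors,
                 noise_sd = noise_sd, cell_size = cell_size),
            class = "synthetic_config")
}

#' The default synthetic 4-class legend
#' @return A `lulc_legend` (forest / fragmented vegetation / pastures and
#'   crops / water).
#' @export
synthetic_legend <- function() {
  lulc_legend(1:4, c("forest", "fragmented vegetation", "pastures and crops",
                     "water"))
}

# Standardized smooth Gaussian random field (zero mean, unit sd). The blur
# kernel is capped at the grid size so strong smoothing works on small grids.
smooth_field <- function(nr, nc, sigma) {
  radius <- min(2 * ceiling(3 * sigma) + 1, 2 * ((min(nr, nc) - 1) %/% 2) + 1)
  f <- EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc), sigma = sigma,
                      radius = radius)
  f <- matrix(as.numeric(f), nr, nc)
  (f - mean(f)) / stats::sd(f)
}

# Deterministic accessibility plane in [0, 1], increasing to the top-right.
gradient_field <- function(nr, nc) {
  g <- outer(rev(seq_len(nr)) / nr, seq_len(nc) / nc, "+") / 2
  (g - min(g)) / (max(g) - min(g))
}

#' Generate the initial synthetic cover map
#'
#' Argmax over per-class smoothed Gaussian random fields, with additive
#' offsets calibrated so class frequencies approach the configured priors,
#' and an accessibility bias on the pasture class (pastures concentrate on
#' accessible land, so the gradient driver associates with the cover map as
#' real accessibility drivers do). Deterministic under the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return An `lulc_map`.
#' @export
generate_initial_map <- function(cfg) {
  nr <- cfg$grid_size[1]; nc <- cfg$grid_size[2]
  leg <- cfg$true_matrix$legend
  k <- nrow(leg)
  set.seed(cfg$seed)
  fields <- lapply(seq_len(k), function(i) smooth_field(nr, nc, cfg$patchiness))
  g <- gradient_field(nr, nc)
  gstd <- (g - mean(g)) / stats::sd(g)
  past <- grep("pasture", leg$name)
  if (length(past) == 1) fields[[past]] <- fields[[past]] + 1.2 * gstd
  off <- rep(0, k)
  v <- NULL
  for (it in 1:100) {
    stack <- vapply(seq_len(k), function(i) as.numeric(fields[[i]] + off[i]),
                    numeric(nr * nc))
    v <- max.col(stack, ties.method = "first")
    freq <- tabulate(v, nbins = k) / (nr * nc)
    if (all(abs(freq - cfg$priors) < 0.005) && all(freq > 0)) break
    off <- off + 0.6 * log(cfg$priors / pmax(freq, 0.5 / (nr * nc)))
  }
  lulc_map(matrix(as.integer(v), nr, nc), leg, cell_size = cfg$cell_size)
}

#' Generate the synthetic driver layers
#'
#' Builds each configured driver: `distance_seeded` layers reuse
#' [distance_to_class()] on the supplied map, `gradient` is the deterministic
#' accessibility plane, and `random_field` layers are smoothed noise with no
#' planted association. Deterministic under the config seed.
#'
#' @param map the `lulc_map` the drivers accompany.
#' @param cfg a [synthetic_config()].
#' @return Named list of `driver_layer`s in `driver_spec` order.
#' @export
generate_drivers <- function(map, cfg) {
  nr <- nrow(map$values); nc <- ncol(map$values)
  out <- list()
  for (i in seq_along(cfg$driver_spec)) {
    ds <- cfg$driver_spec[[i]]
    layer <- switch(ds$kind,
      distance_seeded = {
        d <- distance_to_class(map, ds$class_code)
        d$name <- ds$name
        d
      },
      gradient = driver_layer(ds$name, gradient_field(nr, nc), kind = "static"),
      random_field = {
        set.seed(cfg$seed + 1000L + i)
        driver_layer(ds$name, smooth_field(nr, nc, cfg$patchiness),
                     kind = "static")
      },
      stop("unknown driver kind: ", ds$kind))
    out[[ds$name]] <- layer
  }
  out
}

#' The planted transition potential surface
#'
#' The logistic rule the generator uses to decide which cells change first:
#' `sigma(sum_k w_k (z_k - 0.5))` over min-max standardized driver layers,
#' with the configured effect weights.
#'
#' @param drivers list of driver layers from [generate_drivers()].
#' @param cfg a [synthetic_config()].
#' @return A numeric matrix of potentials in (0, 1).
#' @export
planted_potential <- function(drivers, cfg) {
  z_sum <- 0
  for (ds in cfg$driver_spec) {
    if (ds$effect_weight == 0) next
    v <- drivers[[ds$name]]$values
    fin <- is.finite(v)
    z <- (v - min(v[fin])) / max(max(v[fin]) - min(v[fin]), 1e-12)
    z[!fin] <- 1
    z_sum <- z_sum + ds$effect_weight * (z - 0.5)
  }
  dims <- dim(drivers[[1]]$values)
  if (!is.matrix(z_sum)) z_sum <- matrix(z_sum, dims[1], dims[2])
  sigmoid(z_sum)
}

# Per-destination preference surfaces: smooth seeded fields in [0, 1], one
# per legend class. They decide which destination a changing cell moves to,
# both in the generator and (scaled into the true potentials) for the
# allocator, so closure does not hinge on an unreproducible random draw.
destination_preferences <- function(cfg) {
  nr <- cfg$grid_size[1]; nc <- cfg$grid_size[2]
  k <- nrow(cfg$true_matrix$legend)
  lapply(seq_len(k), function(j) {
    set.seed(cfg$seed + 2000L + j)
    f <- smooth_field(nr, nc, cfg$patchiness)
    (f - min(f)) / (max(f) - min(f))
  })
}

#' Simulate the landscape forward under the true matrix
#'
#' Per source class, the number of cells moving to each destination follows
#' the true matrix row by largest-remainder apportionment (so the planted
#' matrix is recovered in expectation); *which* cells change is decided by
#' ranking on the planted potential plus Gaussian jitter (`noise_sd`), so
#' higher-potential cells change first. Each changing cell's destination is
#' the quota-limited argmax of smooth per-destination preference surfaces
#' (see [true_potentials()]). Deterministic under the config seed.
#'
#' @param map_t0 the initial `lulc_map`.
#' @param cfg a [synthetic_config()].
#' @param drivers optional driver list (regenerated from `map_t0` if absent).
#' @return The later-date `lulc_map`; attribute `changed` holds the logical
#'   change mask.
#' @export
forward_simulate <- function(map_t0, cfg, drivers = NULL) {
  if (is.null(drivers)) drivers <- generate_drivers(map_t0, cfg)
  p <- cfg$true_matrix$p
  leg <- cfg$true_matrix$legend
  v <- map_t0$values
  k <- nrow(p)
  # exact per-transition cell counts from the true matrix rows
  dem <- integer(0)
  for (i in seq_len(k)) {
    n_i <- sum(v == i)
    if (!n_i) next
    counts <- largest_remainder(n_i * p[i, ])
    for (j in seq_len(k))
      if (i != j && counts[j] > 0)
        dem[transition_key(leg$name[i], leg$name[j])] <- counts[j]
  }
  # place the change by ranked allocation on the jittered true potentials:
  # higher planted potential changes first, up to the selection noise
  pots <- true_potentials(list(potential = planted_potential(drivers, cfg),
                               cfg = cfg))
  set.seed(cfg$seed + 7L)
  jit <- matrix(stats::rnorm(length(v), 0, cfg$noise_sd), nrow(v))
  pots <- lapply(pots, function(m) pmax(m + jit, 1e-6))
  out <- allocate_step(map_t0, pots, dem, seed = cfg$seed + 8L)$map
  attr(out, "changed") <- out$values != v
  out
}

#' The true per-transition potential rasters
#'
#' The generator's ground-truth transition potentials: the planted logistic
#' potential blended with the destination-preference surface of each target
#' class, `(s + 0.1 pref_j) / 1.1`, for every off-diagonal transition with
#' nonzero probability. Feeding these to the allocator reproduces the
#' generator's choices up to the selection jitter.
#'
#' @param land a [synthetic_landscape()] bundle (or a list with `potential`
#'   and `cfg`).
#' @return Named list of potential matrices, names `"from -> to"`.
#' @export
true_potentials <- function(land) {
  cfg <- land$cfg
  pref <- destination_preferences(cfg)
  leg <- cfg$true_matrix$legend
  p <- cfg$true_matrix$p
  out <- list()
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (i != j && p[i, j] > 0)
      out[[transition_key(leg$name[i], leg$name[j])]] <-
        (land$potential + 0.1 * pref[[j]]) / 1.1
  }
  out
}

#' Generate a complete synthetic landscape bundle
#'
#' Convenience wrapper: initial map, drivers, later map, planted potential.
#'
#' @param cfg a [synthetic_config()] (default configuration if omitted).
#' @return List with `map_t0`, `map_t1`, `drivers`, `potential`, `cfg`.
#' @export
synthetic_landscape <- function(cfg = synthetic_config()) {
  map_t0 <- generate_initial_map(cfg)
  drivers <- generate_drivers(map_t0, cfg)
  map_t1 <- forward_simulate(map_t0, cfg, drivers)
  list(map_t0 = map_t0, map_t1 = map_t1, drivers = drivers,
       potential = planted_potential(drivers, cfg), cfg = cfg)
}
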