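#' Row-stochastic LULC transition matrix
#'
#' @param p K x K numeric matrix of transition probabilities, rows = source
#'   class, columns = destination class, in legend order.
#' @param interval_years interval the probabilities refer to.
#' @param legend the companion [lulc_legend()].
#' @param normalize renormalize rows to sum exactly 1 (default TRUE).
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(p, interval_years, legend, normalize = TRUE) {
  p <- as.matrix(p)
  k <- nrow(legend)
  if (!all(dim(p) == k)) stop("matrix must be ", k, "x", k, " in legend order")
  if (any(p < 0)) stop("negative transition probability")
  rs <- rowSums(p)
  if (any(rs == 0)) stop("row of zeros (class ", which(rs == 0)[1], ")")
  if (normalize) p <- p / rs
  if (any(abs(rowSums(p) - 1) > 1e-9)) stop("rows do not sum to 1")
  dimnames(p) <- list(legend$name, legend$name)
  structure(list(p = p, interval_years = interval_years, legend = legend),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", nrow(x$p), " classes over ", x$interval_years,
      " year(s)\n", sep = "")
  print(round(x$p, 4))
  invisible(x)
}

#' Per-class area vector
#' @param area_ha numeric vector of areas in hectares, legend order.
#' @param legend an `lulc_legend`.
#' @param year calendar year the areas refer to.
#' @return An object of class `area_vector` (named numeric with attributes).
#' @export
area_vector <- function(area_ha, legend, year = NA_integer_) {
  if (length(area_ha) != nrow(legend)) stop("length must match legend")
  if (any(area_ha < 0)) stop("areas must be >= 0")
  structure(stats::setNames(as.numeric(area_ha), legend$name),
            year = as.integer(year), legend = legend, class = "area_vector")
}

#' Estimate the transition matrix from a cross-tabulation
#'
#' Maximum-likelihood row estimates p_ij = n_ij / n_i. A class absent at the
#' earlier date (empty row) gets an identity row with a warning.
#'
#' @param ct a `crosstab` (see [cross_tabulate()]).
#' @return A [transition_matrix()] with the crosstab's interval.
#' @export
estimate_matrix <- function(ct) {
  counts <- ct$counts
  rs <- rowSums(counts)
  p <- counts / ifelse(rs == 0, 1, rs)
  empty <- rs == 0
  if (any(empty)) {
    warning("class(es) absent at t0 get identity rows: ",
            paste(rownames(counts)[empty], collapse = ", "))
    p[empty, ] <- 0
    diag(p)[empty] <- 1
  }
  transition_matrix(p, ct$interval_years, ct$legend, normalize = TRUE)
}

#' Annualize a transition matrix
#'
#' Computes the matrix root P_a with P_a^interval = P via eigendecomposition.
#' Small negative or complex artefacts of the root are clipped to zero and
#' rows renormalized; the pre-repair reconstruction error is checked against
#' `tol` and the repair magnitude stored in attribute `repair`.
#'
#' @param m a `transition_matrix`.
#' @param tol maximum Frobenius reconstruction error before repair.
#' @return A `transition_matrix` with `interval_years = 1`.
#' @export
annualize <- function(m, tol = 1e-6) {
  t_int <- m$interval_years
  if (t_int == 1) return(m)
  e <- eigen(m$p)
  if (any(Mod(e$values) < 1e-12))
    stop("matrix not invertible; consider subdividing the interval")
  if (any(Re(e$values) <= 0 & abs(Im(e$values)) < 1e-12))
    stop("negative real eigenvalue: no real matrix root; ",
         "consider subdividing the interval")
  root_vals <- as.complex(e$values)^(1 / t_int)
  a_raw <- e$vectors %*% diag(root_vals, nrow = length(root_vals)) %*% solve(e$vectors)
  if (max(abs(Im(a_raw))) > 1e-8)
    stop("complex matrix root (non-diagonalizable or strongly rotating matrix); ",
         "consider subdividing the interval")
  a_raw <- Re(a_raw)
  recon <- matpow(a_raw, t_int)
  err <- sqrt(sum((recon - m$p)^2))
  if (err > tol)
    stop("annualization reconstruction error ", format(err),
         " exceeds tolerance ", tol)
  a <- pmax(a_raw, 0)
  a <- a / rowSums(a)
  out <- transition_matrix(a, 1, m$legend, normalize = FALSE)
  attr(out, "repair") <- sqrt(sum((a - a_raw)^2))
  out
}

matpow <- function(p, n) {
  out <- diag(nrow(p))
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% base
    base <- base %*% base
    n <- n %/% 2
  }
  out
}

#' Project a transition matrix over a number of years
#'
#' @param m a `transition_matrix` (any interval; the power is in units of the
#'   matrix's own interval when `units = "intervals"`, in years when the
#'   matrix is annual).
#' @param years non-negative integer number of years (must be a multiple of
#'   the matrix interval).
#' @return A `transition_matrix` covering `years`.
#' @export
project_matrix <- function(m, years) {
  if (years < 0 || years != round(years)) stop("years must be a non-negative integer")
  if (years == 0)
    return(transition_matrix(diag(nrow(m$p)), 0, m$legend, normalize = FALSE))
  if (years %% m$interval_years != 0)
    stop("years must be a multiple of the matrix interval (",
         m$interval_years, "); annualize first")
  n <- years / m$interval_years
  transition_matrix(matpow(m$p, n), years, m$legend, normalize = TRUE)
}

#' Class-area demand implied by a transition matrix
#'
#' area_j(t1) = sum_i area_i(t0) p_ij. Total area is conserved because rows
#' sum to one.
#'
#' @param area_t0 an [area_vector()].
#' @param m a `transition_matrix` with the same legend.
#' @return An `area_vector` at `year(t0) + interval`.
#' @export
demand <- function(area_t0, m) {
  if (!same_legend(attr(area_t0, "legend"), m$legend)) stop("legend mismatch")
  out <- as.numeric(area_t0 %*% m$p)
  yr <- attr(area_t0, "year")
  area_vector(out, m$legend,
              year = if (is.na(yr)) NA_integer_ else yr + m$interval_years)
}

#' Load an externally specified scenario matrix
#'
#' Reads a K x K probability table (e.g. a printed scenario matrix) and
#' renormalizes each row to sum to one; printed tables often sum to 0.98-1.00
#' from rounding. The per-row renormalization factors are stored in attribute
#' `renorm_factors`.
#'
#' @param table a K x K numeric matrix/data frame, or a CSV path whose first
#'   column holds class names.
#' @param legend the companion legend.
#' @param interval_years interval the matrix refers to.
#' @return A `transition_matrix`.
#' @export
load_scenario_matrix <- function(table, legend, interval_years) {
  if (is.character(table)) {
    df <- utils::read.csv(table, check.names = FALSE, stringsAsFactors = FALSE)
    table <- as.matrix(df[, -1, drop = FALSE])
    rownames(table) <- df[[1]]
  }
  p <- as.matrix(table)
  if (any(p < 0)) stop("negative entry in scenario matrix")
  rs <- rowSums(p)
  if (any(rs == 0)) stop("row of zeros in scenario matrix")
  out <- transition_matrix(p, interval_years, legend, normalize = TRUE)
  attr(out, "renorm_factors") <- stats::setNames(1 / rs, legend$name)
  out
}

#' Annual forest-loss trajectory for a scenario
#'
#' Builds the year-by-year gross forest-loss schedule from 2017 to the
#' horizon:
#' * `trend`: constant at the 2002-2016 mean annual loss.
#' * `extractivist`: linear ramp from the 2008-2016 mean annual loss up to
#'   1.4 x that baseline at the horizon (a 40% increase by 2040).
#' * `sustainable`: the 2002-2016 baseline times a multiplier ramping
#'   linearly from 0.20 (an immediate 80% reduction) down to 0.01 (a 99%
#'   reduction) at the horizon.
#'
#' @param scenario `"trend"`, `"extractivist"` or `"sustainable"`.
#' @param baseline_2002_2016 mean annual forest loss (ha/yr) over 2002-2016.
#' @param baseline_2008_2016 mean annual forest loss (ha/yr) over 2008-2016
#'   (required for the extractivist scenario).
#' @param horizon final year (default 2040).
#' @param start first projected year (default 2017).
#' @param extractivist_mode `"ramp"` (default; year-to-year increase reaching
#'   +40% at the horizon) or `"jump"` (constant +40% from the first year).
#' @return An object of class `loss_trajectory`: data frame `year`,
#'   `loss_ha`, with the scenario and baseline as attributes.
#' @export
loss_trajectory <- function(scenario = c("trend", "extractivist", "sustainable"),
                            baseline_2002_2016, baseline_2008_2016 = NULL,
                            horizon = 2040, start = 2017,
                            extractivist_mode = c("ramp", "jump")) {
  scenario <- match.arg(scenario)
  extractivist_mode <- match.arg(extractivist_mode)
  if (baseline_2002_2016 <= 0) stop("baseline must be > 0")
  years <- seq(start, horizon)
  f <- if (horizon == start) 0 else (years - start) / (horizon - start)
  loss <- switch(scenario,
    trend = rep(baseline_2002_2016, length(years)),
    extractivist = {
      if (is.null(baseline_2008_2016) || baseline_2008_2016 <= 0)
        stop("extractivist scenario needs baseline_2008_2016 > 0")
      if (extractivist_mode == "ramp")
        baseline_2008_2016 * (1 + 0.4 * f)
      else
        rep(1.4 * baseline_2008_2016, length(years))
    },
    sustainable = baseline_2002_2016 * (0.20 + (0.01 - 0.20) * f)
  )
  structure(data.frame(year = years, loss_ha = loss),
            scenario = scenario,
            baseline_mean_ha_per_year = baseline_2002_2016,
            class = c("loss_trajectory", "data.frame"))
}

#' Calibrate a transition matrix to a forest-loss trajectory
#'
#' Scales the off-diagonal entries of the forest rows of the annual matrix by
#' a common factor (the diagonal absorbing the complement) and iterates until
#' the cumulative forest loss implied by stepping the class areas annually to
#' the horizon matches the trajectory's cumulative loss within `tol`
#' (relative).
#'
#' @param m a `transition_matrix` (annualized internally if needed).
#' @param area_t0 an [area_vector()] at the trajectory's start.
#' @param traj a [loss_trajectory()].
#' @param forest_classes class names counted as forest; default: every legend
#'   name containing "forest".
#' @param tol relative tolerance on cumulative loss (default 0.005).
#' @param max_iter iteration cap (default 100).
#' @return An annual `transition_matrix` whose implied cumulative forest loss
#'   matches the trajectory; attribute `scale_factor` holds the final factor.
#' @export
calibrate_matrix_to_trajectory <- function(m, area_t0, traj,
                                           forest_classes = NULL,
                                           tol = 0.005, max_iter = 100) {
  if (is.null(forest_classes))
    forest_classes <- grep("forest", m$legend$name, value = TRUE)
  if (!length(forest_classes)) stop("no forest classes identified in legend")
  fr <- match(forest_classes, m$legend$name)
  if (anyNA(fr)) stop("unknown forest class name")
  ann <- if (m$interval_years == 1) m else annualize(m)
  target <- sum(traj$loss_ha)
  n_years <- nrow(traj)
  implied_loss <- function(p) {
    a <- as.numeric(area_t0); total <- 0
    nonf <- setdiff(seq_len(ncol(p)), fr)
    for (s in seq_len(n_years)) {
      total <- total + sum(a[fr] * rowSums(p[fr, nonf, drop = FALSE]))
      a <- as.numeric(a %*% p)
    }
    total
  }
  if (target == 0) {
    p <- ann$p
    p[fr, ] <- 0
    diag(p)[fr] <- 1
    out <- transition_matrix(p, 1, m$legend, normalize = FALSE)
    attr(out, "scale_factor") <- 0
    return(out)
  }
  a_fac <- 1
  p0 <- ann$p
  for (it in seq_len(max_iter)) {
    p <- p0
    off <- p[fr, , drop = FALSE] * a_fac
    for (j in seq_along(fr)) off[j, fr[j]] <- 0
    if (any(rowSums(off) > 1))
      stop("trajectory demands more loss than the matrix rows can carry")
    p[fr, ] <- off
    diag(p)[fr] <- 1 - rowSums(off)
    cur <- implied_loss(p)
    resid <- abs(cur - target) / target
    if (resid <= tol) {
      out <- transition_matrix(p, 1, m$legend, normalize = FALSE)
      attr(out, "scale_factor") <- a_fac
      return(out)
    }
    a_fac <- a_fac * target / cur
  }
  stop("calibration did not converge; last relative residual ", format(resid))
}

#' Write a transition matrix to CSV (legend-ordered rows/cols)
#' @param m a `transition_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(class = rownames(m$p), m$p, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
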