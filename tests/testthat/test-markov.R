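test_that("matrix estimation follows row proportions and flags empty rows", {
  leg <- two_class_legend()
  m <- toy_map(matrix(1:2, 4, 4), legend = leg)
  expect_equal(estimate_matrix(cross_tabulate(m, m))$p, diag(2),
               ignore_attr = TRUE)
  ct <- cross_tabulate(m, m)
  ct$counts <- matrix(c(90L, 0L, 10L, 0L), 2,
                      dimnames = dimnames(ct$counts))
  expect_warning(est <- estimate_matrix(ct), "identity rows")
  expect_equal(unname(est$p[1, ]), c(0.9, 0.1))
  expect_equal(unname(est$p[2, ]), c(0, 1))
})

test_that("annualization inverts repeated squaring on clean matrices", {
  leg <- two_class_legend()
  m <- transition_matrix(rbind(c(0.96, 0.04), c(0, 1)), 2, leg)
  ann <- annualize(m)
  expect_equal(ann$p %*% ann$p, m$p, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(ann$p), c(1, 1), ignore_attr = TRUE)
  # identity stays identity
  id <- transition_matrix(diag(2), 5, leg)
  expect_equal(annualize(id)$p, diag(2), ignore_attr = TRUE)
  # a rotation-like matrix with negative eigenvalue is rejected
  bad <- transition_matrix(rbind(c(0.05, 0.95), c(0.95, 0.05)), 2, leg)
  expect_error(annualize(bad), "eigenvalue|subdividing")
})

test_that("projection powers the matrix and preserves absorbing rows", {
  leg <- two_class_legend()
  ann <- annualize(transition_matrix(rbind(c(0.96, 0.04), c(0, 1)), 2, leg))
  expect_equal(project_matrix(ann, 0)$p, diag(2), ignore_attr = TRUE)
  expect_equal(project_matrix(ann, 2)$p,
               rbind(c(0.96, 0.04), c(0, 1)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # absorbing class keeps a unit row at any horizon
  expect_equal(unname(project_matrix(ann, 7)$p[2, ]), c(0, 1))
})

test_that("demand moves areas by the matrix and conserves the total", {
  leg <- two_class_legend()
  a <- area_vector(c(100, 0), leg, 2016)
  m <- transition_matrix(rbind(c(0.8, 0.2), c(0, 1)), 24, leg)
  d <- demand(a, m)
  expect_equal(as.numeric(d), c(80, 20))
  expect_equal(attr(d, "year"), 2040L)
  id <- transition_matrix(diag(2), 1, leg)
  expect_equal(as.numeric(demand(a, id)), c(100, 0))
  set.seed(2)
  for (i in 1:10) {
    p <- matrix(stats::runif(4), 2); p <- p / rowSums(p)
    a2 <- area_vector(stats::runif(2, 0, 1e6), leg)
    expect_equal(sum(demand(a2, transition_matrix(p, 1, leg))), sum(a2))
  }
})

test_that("scenario matrices renormalize printed rounded rows", {
  t4 <- load_fixture("table4")
  expect_equal(rowSums(t4$p), rep(1, 7), ignore_attr = TRUE)
  expect_equal(t4$p["Amazon forests", "Amazon forests"], 0.67 / 0.99)
  fac <- attr(t4, "renorm_factors")
  expect_equal(unname(fac["Amazon forests"]), 1 / 0.99)
  # already-normalized rows pass through unchanged
  leg <- two_class_legend()
  m <- load_scenario_matrix(rbind(c(0.5, 0.5), c(0, 1)), leg, 24)
  expect_equal(unname(m$p), rbind(c(0.5, 0.5), c(0, 1)))
  expect_error(load_scenario_matrix(rbind(c(-0.1, 1.1), c(0, 1)), leg, 24),
               "negative")
  expect_error(load_scenario_matrix(rbind(c(0, 0), c(0, 1)), leg, 24),
               "zeros")
})

test_that("loss trajectories encode the three scenario narratives", {
  tr <- loss_trajectory("trend", 1e5)
  expect_equal(tr$year, 2017:2040)
  expect_true(all(tr$loss_ha == 1e5))
  ex <- loss_trajectory("extractivist", 1e5, baseline_2008_2016 = 9e4)
  expect_equal(ex$loss_ha[1], 9e4)
  expect_equal(ex$loss_ha[24] / ex$loss_ha[1], 1.4)
  expect_true(all(diff(ex$loss_ha) > 0))
  exj <- loss_trajectory("extractivist", 1e5, 9e4, extractivist_mode = "jump")
  expect_true(all(exj$loss_ha == 1.4 * 9e4))
  su <- loss_trajectory("sustainable", 1e5)
  expect_equal(su$loss_ha[1] / 1e5, 0.20)
  expect_equal(su$loss_ha[24] / 1e5, 0.01)
  expect_true(all(su$loss_ha >= 0))
  expect_error(loss_trajectory("trend", -5), "baseline")
  expect_error(loss_trajectory("apocalypse", 1), "arg")
})

test_that("trajectory calibration recovers the closed-form scale factor", {
  leg <- lulc_legend(1:2, c("forest", "other"))
  m <- transition_matrix(rbind(c(0.9, 0.1), c(0, 1)), 1, leg)
  a <- area_vector(c(100, 0), leg, 2016)
  # one-year horizon: implied loss 10 ha; target 5 ha -> scale 0.5
  traj <- loss_trajectory("trend", 5, horizon = 2017, start = 2017)
  cal <- calibrate_matrix_to_trajectory(m, a, traj, forest_classes = "forest")
  expect_equal(attr(cal, "scale_factor"), 0.5, tolerance = 0.005)
  expect_equal(unname(cal$p[1, ]), c(0.95, 0.05), tolerance = 1e-3)
  # fixed point: a trajectory equal to the implied loss returns the input
  traj0 <- loss_trajectory("trend", 10, horizon = 2017, start = 2017)
  cal0 <- calibrate_matrix_to_trajectory(m, a, traj0, forest_classes = "forest")
  expect_equal(cal0$p, m$p, tolerance = 0.01)
  # zero trajectory: forest rows become identity
  trajz <- loss_trajectory("trend", 1, horizon = 2017, start = 2017)
  trajz$loss_ha <- 0
  calz <- calibrate_matrix_to_trajectory(m, a, trajz, forest_classes = "forest")
  expect_equal(unname(calz$p[1, ]), c(1, 0))
})

test_that("every matrix operation returns row-stochastic output", {
  set.seed(4)
  leg <- lulc_legend(1:3, c("forest", "mixed", "open"))
  for (i in 1:8) {
    # an exact 14-year power of a diagonally dominant annual matrix, the
    # structure annual LULC persistence produces
    q <- matrix(stats::runif(9), 3)
    a <- 0.9 * diag(3) + 0.1 * q / rowSums(q)
    m <- transition_matrix(lulcsim:::matpow(a, 14), 14, leg)
    ann <- annualize(m)
    expect_equal(rowSums(ann$p), rep(1, 3), ignore_attr = TRUE)
    expect_equal(rowSums(project_matrix(ann, 14)$p), rep(1, 3),
                 ignore_attr = TRUE, tolerance = 1e-9)
    # annualize-then-power round trip
    expect_equal(project_matrix(ann, 14)$p, m$p, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})
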