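test_that("cell demand follows the matrix and matches the exact recursion", {
  leg <- two_class_legend()
  m100 <- toy_map(matrix(c(rep(1L, 100), rep(2L, 44)), 12), legend = leg)
  id <- transition_matrix(diag(2), 1, leg)
  expect_equal(nrow(demand_to_cells(id, m100, 3)), 0)
  p <- transition_matrix(rbind(c(0.9, 0.1), c(0, 1)), 1, leg)
  d1 <- demand_to_cells(p, m100, 1)
  expect_equal(d1$cells, 10L)
  # 3-step toy against the real-valued recursion oracle, within 1 cell
  d3 <- demand_to_cells(p, m100, 3)
  n <- 100
  for (s in 1:3) {
    expected <- n * 0.1
    got <- d3$cells[d3$step == s]
    expect_lte(abs(got - expected), 1)
    n <- n * 0.9
  }
})

test_that("allocation takes the highest-potential cells exactly", {
  leg <- two_class_legend()
  cur <- toy_map(matrix(c(rep(1L, 5), rep(2L, 4)), 3), legend = leg)
  pot <- matrix(0, 3, 3)
  pot[1:5] <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  res <- allocate_step(cur, list("alpha -> beta" = pot),
                       c("alpha -> beta" = 2L), seed = 1)
  expect_equal(which(res$map$values != cur$values), c(1L, 2L))
  expect_equal(res$ledger$achieved, 2L)
  expect_equal(res$ledger$unmet, 0L)
  # zero demand leaves the map untouched
  res0 <- allocate_step(cur, list("alpha -> beta" = pot),
                        c("alpha -> beta" = 0L), seed = 1)
  expect_identical(res0$map$values, cur$values)
})

test_that("allocation properties hold on random 8x8 grids", {
  leg <- two_class_legend()
  set.seed(88)
  for (rep in 1:10) {
    cur <- toy_map(matrix(sample(1:2, 64, TRUE), 8), legend = leg)
    pot <- matrix(stats::runif(64), 8)
    n_elig <- sum(cur$values == 1L)
    d <- sample.int(max(n_elig, 1), 1)
    res <- allocate_step(cur, list("alpha -> beta" = pot),
                         c("alpha -> beta" = d), seed = rep)
    changed <- res$map$values != cur$values
    expect_equal(sum(changed), min(d, n_elig))
    expect_equal(res$ledger$achieved + res$ledger$unmet, res$ledger$demanded)
    # changed cells carry at least the potential of unchanged eligible cells
    if (any(changed) && any(!changed & cur$values == 1L))
      expect_gte(min(pot[changed]),
                 max(pot[!changed & cur$values == 1L]) - 1e-12)
    # monotonicity: more demand never allocates fewer cells
    if (d > 1) {
      res_lo <- allocate_step(cur, list("alpha -> beta" = pot),
                              c("alpha -> beta" = d - 1L), seed = rep)
      expect_lte(res_lo$ledger$achieved, res$ledger$achieved)
    }
  }
})

test_that("multi-transition conflicts resolve by highest potential", {
  leg <- lulc_legend(1:3, c("forest", "mixed", "open"))
  cur <- toy_map(matrix(1L, 2, 2), legend = leg)
  pot_a <- matrix(c(0.9, 0.2, 0.2, 0.2), 2)  # forest -> mixed
  pot_b <- matrix(c(0.5, 0.8, 0.1, 0.1), 2)  # forest -> open
  res <- allocate_step(cur,
                       list("forest -> mixed" = pot_a,
                            "forest -> open" = pot_b),
                       c("forest -> mixed" = 1L, "forest -> open" = 1L),
                       seed = 3)
  expect_equal(res$map$values[1, 1], 2L)  # cell 1 prefers mixed (0.9 > 0.5)
  expect_equal(res$map$values[2, 1], 3L)  # cell 2 prefers open (0.8 > 0.2)
  expect_equal(sum(res$ledger$unmet), 0L)
})

test_that("simulation conserves cells, satisfies ledgers, and is reproducible", {
  land <- default_land()
  pots <- true_potentials(land)
  spec <- bare_scenario(land$cfg$true_matrix, 14, annual_steps = TRUE)
  res <- simulate_scenario(spec, land$map_t0, pots, start_year = 0,
                           output_years = c(7, 14), seed = 11)
  res2 <- simulate_scenario(spec, land$map_t0, pots, start_year = 0,
                            output_years = c(7, 14), seed = 11)
  expect_identical(res$maps[["14"]]$values, res2$maps[["14"]]$values)
  expect_identical(res$ledger, res2$ledger)
  expect_equal(length(res$maps[["14"]]$values), length(land$map_t0$values))
  expect_true(all(res$ledger$achieved + res$ledger$unmet ==
                    res$ledger$demanded))
  # per-class deltas equal inflow minus outflow, step by step
  led <- res$ledger[res$ledger$step == 1, ]
  m1 <- simulate_scenario(spec, land$map_t0, pots, start_year = 0,
                          output_years = 1, seed = 11)$maps[["1"]]
  for (cl in land$cfg$true_matrix$legend$name) {
    delta <- sum(m1$values == legend_code(m1$legend, cl)) -
      sum(land$map_t0$values == legend_code(m1$legend, cl))
    expect_equal(delta, sum(led$achieved[led$to == cl]) -
                   sum(led$achieved[led$from == cl]))
  }
})

test_that("an identity matrix simulates to an unchanged landscape", {
  land <- default_land()
  id <- transition_matrix(diag(4), 1, land$cfg$true_matrix$legend)
  spec <- bare_scenario(id, 5)
  res <- simulate_scenario(spec, land$map_t0, true_potentials(land),
                           start_year = 0, output_years = 5, seed = 2)
  expect_identical(res$maps[["5"]]$values, land$map_t0$values)
})

test_that("constrained transitions never fire, at any demand", {
  land <- default_land()
  leg <- land$cfg$true_matrix$legend
  all_true <- mask_layer("protected", matrix(TRUE, 128, 128))
  constraints <- list(list(
    mask = all_true,
    transitions = list(c(from = "forest", to = "fragmented vegetation"),
                       c(from = "forest", to = "pastures and crops"))))
  spec <- bare_scenario(land$cfg$true_matrix, 14, annual_steps = FALSE,
                        constraints = constraints)
  res <- simulate_scenario(spec, land$map_t0, true_potentials(land),
                           start_year = 0, output_years = 14, seed = 4)
  led <- res$ledger
  floss <- led[led$from == "forest", ]
  expect_gt(sum(floss$demanded), 0)
  expect_equal(sum(floss$achieved), 0L)
  expect_equal(sum(floss$unmet), sum(floss$demanded))
  # no forest cell changed
  fmask <- land$map_t0$values == 1L
  expect_true(all(res$maps[["14"]]$values[fmask] == 1L))
})

test_that("unmet demand is carried forward between steps", {
  leg <- two_class_legend()
  cur <- toy_map(matrix(c(rep(1L, 3), rep(2L, 13)), 4), legend = leg)
  # demand 2/step but only 1 positive-potential cell available per step
  pot <- matrix(0, 4, 4); pot[1] <- 0.9
  m <- transition_matrix(rbind(c(1 / 3, 2 / 3), c(0, 1)), 1, leg)
  spec <- bare_scenario(m, 2)
  res <- simulate_scenario(spec, cur, list("alpha -> beta" = pot),
                           start_year = 0, output_years = 2, seed = 1)
  led <- res$ledger
  expect_gt(led$unmet[led$step == 1], 0)
  # step-2 demand includes the carried shortfall and cannot be met either
  expect_gte(led$demanded[led$step == 2], led$unmet[led$step == 1])
  res_nc <- simulate_scenario(spec, cur, list("alpha -> beta" = pot),
                              start_year = 0, output_years = 2, seed = 1,
                              carry_unmet = FALSE)
  led_nc <- res_nc$ledger
  expect_lt(led_nc$demanded[led_nc$step == 2], led$demanded[led$step == 2])
})
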