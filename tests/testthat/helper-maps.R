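# Small builders shared across the suite.

two_class_legend <- function() lulc_legend(1:2, c("alpha", "beta"))

# lulc_map from a plain integer matrix with an auto legend
toy_map <- function(values, legend = NULL, cell_size = 60) {
  codes <- sort(unique(as.integer(values[values != 0])))
  if (is.null(legend))
    legend <- lulc_legend(codes, paste0("class", codes))
  lulc_map(matrix(as.integer(values), nrow(values)), legend,
           cell_size = cell_size)
}

# confusion matrix object from raw counts
toy_confusion <- function(counts) {
  k <- nrow(counts)
  leg <- lulc_legend(seq_len(k), paste0("class", seq_len(k)))
  dimnames(counts) <- list(leg$name, leg$name)
  structure(list(counts = counts, legend = leg), class = "confusion_matrix")
}

# crosstab of the printed 14-transition table, at 1 ha cells so the printed
# hectare figures are preserved exactly
table1_crosstab <- function() {
  crosstab_from_table <- get("crosstab_from_table", asNamespace("lulcsim"))
  crosstab_from_table(load_fixture("table1"), amazon_legend(),
                      cell_area_ha = 1, interval_years = 14)
}

# hand-built training set (bypasses sampling) for MLP unit tests
toy_training_set <- function(features, labels, seed = 1) {
  set.seed(seed)
  labels <- factor(labels)
  ranges <- apply(features, 2, range)
  span <- pmax(ranges[2, ] - ranges[1, ], 1e-12)
  feats <- sweep(sweep(features, 2, ranges[1, ]), 2, span, "/")
  split <- character(length(labels))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    tr <- sample(idx, ceiling(length(idx) / 2))
    split[tr] <- "train"
    split[setdiff(idx, tr)] <- "test"
  }
  structure(list(features = feats, labels = labels, split = split,
                 ranges = ranges, classes = levels(labels)),
            class = "training_set")
}

# bare scenario spec for allocator-level tests
bare_scenario <- function(matrix, horizon, annual_steps = TRUE,
                          constraints = list(), incentives = list(),
                          trajectory = NULL, forest_classes = "forest") {
  structure(list(name = "trend", horizon_year = horizon, matrix = matrix,
                 trajectory = trajectory, constraints = constraints,
                 incentives = incentives, forest_classes = forest_classes,
                 annual_steps = annual_steps),
            class = "scenario_spec")
}

# shared landscapes per test run (generation ~1 s each)
default_land <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_landscape(synthetic_config())
    cache
  }
})

default_land_256 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_landscape(synthetic_config(grid_size = c(256, 256)))
    cache
  }
})
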