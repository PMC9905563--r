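#' Sample change/persistence training cells for a submodel
#'
#' For every transition i -> j in `submodel_specs`, cells that changed
#' (class i at t0, j at t1) form one outcome class, and cells that persisted
#' in the source class (i at both dates) form the corresponding persistence
#' class. Up to `n_per_class` cells are drawn per outcome class (all
#' candidates, with a warning, when fewer exist), features are the driver
#' values at the sampled cells min-max standardized to [0, 1], and a 50/50
#' stratified train/test split is fixed.
#'
#' @param map_t0,map_t1 dated `lulc_map`s on the same grid.
#' @param submodel_specs a `transition_specs` data frame (rows of one
#'   submodel).
#' @param drivers list of `driver_layer`s.
#' @param n_per_class cells per outcome class (default 500).
#' @param seed RNG seed; sampling is deterministic under a fixed seed.
#' @return An object of class `training_set`: list with `features` (N x n
#'   matrix in [0,1]), `labels` (factor), `split` ("train"/"test"),
#'   `ranges` (per-driver min/max frozen for prediction), `classes`.
#' @export
sample_training <- function(map_t0, map_t1, submodel_specs, drivers,
                            n_per_class = 500, seed = 1) {
  check_conform(map_t0, map_t1, "map")
  for (d in drivers) check_conform(map_t0, d, d$name)
  set.seed(seed)
  pools <- list()
  for (i in seq_len(nrow(submodel_specs))) {
    from <- legend_code(map_t0$legend, submodel_specs$from[i])
    to <- legend_code(map_t0$legend, submodel_specs$to[i])
    ch <- which(map_t0$values == from & map_t1$values == to)
    if (!length(ch))
      stop("transition '", submodel_specs$from[i], " -> ",
           submodel_specs$to[i], "' has zero changed cells")
    pools[[paste0("change: ", submodel_specs$from[i], " -> ",
                  submodel_specs$to[i])]] <- ch
    pk <- paste0("persistence: ", submodel_specs$from[i])
    if (is.null(pools[[pk]]))
      pools[[pk]] <- which(map_t0$values == from & map_t1$values == from)
  }
  cells <- integer(0); labels <- character(0)
  for (k in names(pools)) {
    pool <- pools[[k]]
    if (length(pool) < n_per_class) {
      warning("class '", k, "' has only ", length(pool),
              " candidate cells; using all of them")
      take <- pool
    } else take <- sample(pool, n_per_class)
    cells <- c(cells, take)
    labels <- c(labels, rep(k, length(take)))
  }
  feats <- vapply(drivers, function(d) d$values[cells], numeric(length(cells)))
  colnames(feats) <- vapply(drivers, `[[`, "", "name")
  ranges <- apply(feats, 2, range)
  span <- pmax(ranges[2, ] - ranges[1, ], 1e-12)
  feats <- sweep(sweep(feats, 2, ranges[1, ]), 2, span, "/")
  labels <- factor(labels)
  split <- character(length(labels))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    tr <- sample(idx, ceiling(length(idx) / 2))
    split[tr] <- "train"; split[setdiff(idx, tr)] <- "test"
  }
  if (any(table(labels, split) == 0))
    stop("a class has no train or no test samples; increase n_per_class")
  structure(list(features = feats, labels = labels, split = split,
                 ranges = ranges, cells = cells, classes = levels(labels)),
            class = "training_set")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a one-hidden-layer perceptron on a training set
#'
#' A multilayer perceptron with one sigmoid hidden layer and sigmoid output
#' nodes (one per outcome class), trained by full-batch backpropagation with
#' momentum on cross-entropy loss. Training runs on the train split with
#' early stopping when test accuracy has not improved for `patience` epochs.
#'
#' @param ts a [sample_training()] result.
#' @param hidden_size hidden neurons; default `ceiling(n_inputs / 2)`.
#' @param learning_rate step size (default 0.01).
#' @param momentum momentum coefficient in [0, 1) (default 0.5).
#' @param epochs epoch cap (default 10000).
#' @param patience early-stop patience in epochs (default 100).
#' @param seed RNG seed for weight initialisation.
#' @return List with `model` (an `mlp_model`: weights, standardization
#'   ranges, class names) and `stats` (a `fit_stats` row: `accuracy_rate`
#'   percent correct on the test split, `skill_measure`).
#' @export
train_mlp <- function(ts, hidden_size = NULL, learning_rate = 0.01,
                      momentum = 0.5, epochs = 10000, patience = 100,
                      seed = 1) {
  x <- ts$features
  n_in <- ncol(x)
  if (is.null(hidden_size)) hidden_size <- max(1L, ceiling(n_in / 2))
  if (hidden_size < 1) stop("hidden_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  classes <- levels(ts$labels)
  n_out <- length(classes)
  y <- vapply(classes, function(k) as.numeric(ts$labels == k),
              numeric(length(ts$labels)))  # one-hot
  tr <- ts$split == "train"; te <- !tr
  set.seed(seed)
  w1 <- matrix(stats::runif((n_in + 1) * hidden_size, -0.5, 0.5), n_in + 1)
  w2 <- matrix(stats::runif((hidden_size + 1) * n_out, -0.5, 0.5), hidden_size + 1)
  v1 <- w1 * 0; v2 <- w2 * 0
  xb_tr <- cbind(1, x[tr, , drop = FALSE]); y_tr <- y[tr, , drop = FALSE]
  xb_te <- cbind(1, x[te, , drop = FALSE])
  lab_te <- ts$labels[te]
  n_tr <- nrow(xb_tr)
  best_acc <- -Inf; best <- list(w1 = w1, w2 = w2); stall <- 0L
  for (ep in seq_len(epochs)) {
    h <- sigmoid(xb_tr %*% w1)
    hb <- cbind(1, h)
    out <- sigmoid(hb %*% w2)
    delta_out <- out - y_tr                       # dCE/dz for sigmoid output
    if (!all(is.finite(delta_out)))
      stop("non-finite loss at epoch ", ep, " (learning_rate ", learning_rate, ")")
    g2 <- crossprod(hb, delta_out) / n_tr
    delta_h <- (delta_out %*% t(w2[-1, , drop = FALSE])) * h * (1 - h)
    g1 <- crossprod(xb_tr, delta_h) / n_tr
    v2 <- momentum * v2 - learning_rate * g2
    v1 <- momentum * v1 - learning_rate * g1
    w2 <- w2 + v2; w1 <- w1 + v1
    if (ep %% 10 == 0 || ep == epochs) {
      pred <- mlp_forward(xb_te, w1, w2)
      acc <- mean(classes[max.col(pred, ties.method = "first")] == lab_te)
      if (acc > best_acc + 1e-12) {
        best_acc <- acc; best <- list(w1 = w1, w2 = w2); stall <- 0L
      } else {
        stall <- stall + 10L
        if (stall >= patience) break
      }
    }
  }
  pred <- mlp_forward(xb_te, best$w1, best$w2)
  acc <- mean(classes[max.col(pred, ties.method = "first")] == lab_te)
  dimnames(best$w1) <- NULL
  dimnames(best$w2) <- NULL
  stats <- data.frame(accuracy_rate = 100 * acc,
                      skill_measure = skill_measure(acc, n_out))
  model <- structure(list(input_names = colnames(x), hidden_size = hidden_size,
                          w1 = best$w1, w2 = best$w2, classes = classes,
                          ranges = ts$ranges, learning_rate = learning_rate,
                          momentum = momentum, epochs_run = ep,
                          rng_seed = seed),
                     class = "mlp_model")
  list(model = model, stats = stats)
}

mlp_forward <- function(xb, w1, w2) {
  sigmoid(cbind(1, sigmoid(xb %*% w1)) %*% w2)
}

#' Chance-corrected skill measure
#'
#' `S = (A - E) / (1 - E)` with expected chance accuracy `E = 1 / n`:
#' 1 for perfect prediction, 0 at chance level, negative below chance.
#'
#' @param accuracy proportion correct in [0, 1].
#' @param n_outcome_classes number of transition + persistence classes (>= 2).
#' @return The skill measure in [-1/(n-1)... 1].
#' @export
skill_measure <- function(accuracy, n_outcome_classes) {
  if (n_outcome_classes < 2) stop("n_outcome_classes must be >= 2")
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]")
  e <- 1 / n_outcome_classes
  (accuracy - e) / (1 - e)
}

#' Predict a transition potential raster
#'
#' Applies a trained model to full driver rasters and returns the output-node
#' activation of the requested transition: a per-cell value in [0, 1] (the
#' sigmoid output), with the model's frozen standardization re-applied and
#' nodata propagated.
#'
#' @param model an `mlp_model`.
#' @param drivers list of `driver_layer`s covering `model$input_names`.
#' @param transition output class to extract: either a full class label
#'   (e.g. `"change: Amazon forests -> pastures and crops"`) or a one-row
#'   `transition_specs` data frame.
#' @param map optional companion `lulc_map`: its nodata cells become `NA`.
#' @return A `potential_raster`: list with `values` (matrix in [0,1]) and
#'   `transition`.
#' @export
predict_potential <- function(model, drivers, transition, map = NULL) {
  if (is.data.frame(transition))
    transition <- paste0("change: ", transition$from[1], " -> ", transition$to[1])
  if (!transition %in% model$classes)
    stop("model has no output for '", transition, "'")
  dnames <- vapply(drivers, `[[`, "", "name")
  miss <- setdiff(model$input_names, dnames)
  if (length(miss)) stop("missing driver layer(s): ", paste(miss, collapse = ", "))
  drivers <- drivers[match(model$input_names, dnames)]
  dims <- dim(drivers[[1]]$values)
  x <- vapply(drivers, function(d) as.numeric(d$values), numeric(prod(dims)))
  span <- pmax(model$ranges[2, ] - model$ranges[1, ], 1e-12)
  x <- sweep(sweep(x, 2, model$ranges[1, ]), 2, span, "/")
  x[!is.finite(x)] <- 0
  out <- mlp_forward(cbind(1, x), model$w1, model$w2)
  v <- matrix(out[, match(transition, model$classes)], dims[1], dims[2])
  if (!is.null(map)) v[!valid_cells(map)] <- NA
  structure(list(values = v, transition = transition),
            class = "potential_raster")
}

#' Serialize / restore an MLP model as JSON
#' @param model an `mlp_model`.
#' @param path file path.
#' @return `path` invisibly / the restored `mlp_model`.
#' @export
write_mlp <- function(model, path) {
  obj <- unclass(model)
  obj$w1 <- as.data.frame(obj$w1)
  obj$w2 <- as.data.frame(obj$w2)
  obj$ranges <- as.data.frame(obj$ranges)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$w1 <- as.matrix(obj$w1); dimnames(obj$w1) <- NULL
  obj$w2 <- as.matrix(obj$w2); dimnames(obj$w2) <- NULL
  obj$ranges <- as.matrix(obj$ranges)
  rownames(obj$ranges) <- NULL
  colnames(obj$ranges) <- obj$input_names
  structure(obj, class = "mlp_model")
}
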