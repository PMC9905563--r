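#' Confusion matrix between an observed and a simulated map
#'
#' Rows are the observed classes, columns the simulated classes; cells nodata
#' in either map are excluded. This is the same cross-tabulation machinery
#' used for change analysis, fixed to the observed-vs-simulated orientation.
#'
#' @param observed,simulated `lulc_map`s on the same grid and legend.
#' @return An object of class `confusion_matrix`: list with `counts`
#'   (rows = observed, cols = simulated) and `legend`.
#' @export
confusion <- function(observed, simulated) {
  ct <- cross_tabulate(observed, simulated, interval_years = 1)
  structure(list(counts = ct$counts, legend = ct$legend),
            class = "confusion_matrix")
}

#' Overall (Cohen's) kappa of a confusion matrix
#'
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the diagonal proportion and
#' p_e the sum of products of matching row/column marginal proportions.
#' When both maps are constant and identical (p_e = 1), agreement is perfect
#' and 1 is returned by convention, with a message.
#'
#' @param cm a `confusion_matrix` (or plain count matrix).
#' @return Overall kappa (<= 1).
#' @export
overall_kappa <- function(cm) {
  counts <- if (inherits(cm, "confusion_matrix")) cm$counts else cm
  n <- sum(counts)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    message("degenerate marginals (p_e = 1): kappa = 1 by convention")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Per-class kappa index of agreement (KIA)
#'
#' The conditional (user's) kappa for one class:
#' `kia_i = (p_ii - p_i x p_.i) / (p_i - p_i x p_.i)` where `p_i` is the
#' class's marginal proportion on the conditioning side (`side = "observed"`:
#' row marginal; `side = "simulated"`: column marginal).
#'
#' @param cm a `confusion_matrix`.
#' @param class_code legend code or class name.
#' @param side `"observed"` (default) or `"simulated"` conditioning.
#' @return KIA (<= 1), or `NA` with a warning for degenerate marginals.
#' @export
per_class_kia <- function(cm, class_code, side = c("observed", "simulated")) {
  side <- match.arg(side)
  counts <- cm$counts
  i <- if (is.character(class_code)) match(class_code, rownames(counts))
       else match(class_code, cm$legend$code)
  if (is.na(i)) stop("unknown class")
  n <- sum(counts)
  pii <- counts[i, i] / n
  pr <- sum(counts[i, ]) / n   # observed marginal
  pc <- sum(counts[, i]) / n   # simulated marginal
  cond <- if (side == "observed") pr else pc
  denom <- cond - pr * pc
  if (abs(denom) < .Machine$double.eps * 4 || cond == 0) {
    warning("degenerate marginal for class '", rownames(counts)[i],
            "': KIA undefined")
    return(NA_real_)
  }
  (pii - pr * pc) / denom
}

#' Full validation report for a simulated map
#'
#' Emits both conditional KIA variants per class (observed-side and
#' simulated-side) plus overall kappa, mirroring the standard two-column
#' agreement report. KIA here is the conditional kappa
#' `(p_ii - p_i p_.i)/(p_i - p_i p_.i)`.
#'
#' @param observed,simulated `lulc_map`s, or `cm` a ready `confusion_matrix`.
#' @param cm optional precomputed confusion matrix.
#' @return An object of class `validation_report`: list with `per_class`
#'   (data frame `class`, `kia_observed`, `kia_simulated`), `overall_kappa`,
#'   `confusion`.
#' @export
validation_report <- function(observed = NULL, simulated = NULL, cm = NULL) {
  if (is.null(cm)) cm <- confusion(observed, simulated)
  classes <- rownames(cm$counts)
  per_class <- data.frame(
    class = classes,
    kia_observed = vapply(classes, function(cl)
      suppressWarnings(per_class_kia(cm, cl, "observed")), numeric(1)),
    kia_simulated = vapply(classes, function(cl)
      suppressWarnings(per_class_kia(cm, cl, "simulated")), numeric(1)),
    row.names = NULL)
  structure(list(per_class = per_class,
                 overall_kappa = overall_kappa(cm),
                 confusion = cm),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> rows = observed, cols = simulated\n")
  print(x$per_class, digits = 3)
  cat("Overall kappa:", round(x$overall_kappa, 4), "\n")
  invisible(x)
}

#' Write a validation report to CSV
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  df <- report$per_class
  df <- rbind(df, data.frame(class = "Overall kappa",
                             kia_observed = report$overall_kappa,
                             kia_simulated = report$overall_kappa))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
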