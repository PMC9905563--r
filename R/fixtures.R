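# Packaged study tables. Fixtures are read-only and checksummed: a mismatch
# means the installation is corrupt, not that the numbers moved.
.fixture_files <- c(
  table1 = "table1_transitions.csv",
  table4 = "table4_bau.csv",
  table5 = "table5_extractivist.csv",
  table6 = "table6_sustainable.csv",
  table7 = "table7_areas.csv"
)

.fixture_md5 <- c(
  table1 = "374e33d84c271338ac0cb820a53cd22d",
  table4 = "f6c8c1c59452fe4711bfab77fcd1e377",
  table5 = "eb8b27ed29009cd0c7ceddfee85906c3",
  table6 = "e11d2ac704caeb10dd2fb63e10253817",
  table7 = "d9cc8cbfb5292c10778b931973e27cfb"
)

#' Load a packaged study table
#'
#' Returns the package's transcriptions of the Colombian Amazon study tables
#' as typed objects:
#' * `table1` — the 14 major 2002-2016 transitions with submodel and area
#'   (data frame `from,to,submodel,area_ha`).
#' * `table4` — the business-as-usual 2016-2040 Markov matrix (a
#'   [transition_matrix()], rows renormalized; printed rows sum to 0.98-1.00
#'   from rounding).
#' * `table5` — the extractivist external matrix. As printed this table is
#'   incomplete (one row missing, one row garbled); affected rows are flagged
#'   in attribute `suspect` and the missing row is filled from the
#'   business-as-usual matrix the external models were derived from.
#' * `table6` — the sustainable-development external matrix.
#' * `table7` — reference-2016 and scenario-2040 class areas (data frame).
#'
#' @param name one of `"table1"`, `"table4"`, `"table5"`, `"table6"`,
#'   `"table7"`.
#' @return See above.
#' @export
load_fixture <- function(name = c("table1", "table4", "table5", "table6", "table7")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixture_files[[name]], package = "lulcsim",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]])))
    stop("fixture checksum mismatch for ", name, ": ", sum)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  leg <- amazon_legend()
  switch(name,
    table1 = {
      out <- df[, c("from", "to", "submodel", "area_ha")]
      class(out) <- c("transition_specs", "data.frame")
      out
    },
    table7 = df,
    {
      suspect <- if ("suspect" %in% names(df)) df$suspect else rep(FALSE, nrow(df))
      df$suspect <- NULL
      stopifnot(identical(df$class, leg$name))
      p <- as.matrix(df[, -1, drop = FALSE])
      rownames(p) <- df$class
      m <- load_scenario_matrix(p, leg, interval_years = 24)
      attr(m, "suspect") <- stats::setNames(suspect, leg$name)
      m
    }
  )
}
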