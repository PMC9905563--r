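#' Class legend for categorical LULC rasters
#'
#' A legend maps small integer class codes to class names. Code 0 is reserved
#' internally for nodata and may not appear in a legend.
#'
#' @param codes integer vector of unique class codes (> 0).
#' @param names character vector of unique class names, same length.
#' @return An object of class `lulc_legend`: a data frame with columns
#'   `code` and `name`.
#' @examples
#' lulc_legend(1:2, c("forest", "pasture"))
#' @export
lulc_legend <- function(codes, names) {
  codes <- as.integer(codes)
  names <- as.character(names)
  if (length(codes) != length(names))
    stop("codes and names must have the same length")
  if (length(codes) < 2)
    stop("a legend needs at least 2 entries")
  if (anyDuplicated(codes)) stop("legend codes must be unique")
  if (anyDuplicated(names)) stop("legend names must be unique")
  if (any(codes <= 0)) stop("legend codes must be positive (0 is reserved for nodata)")
  structure(data.frame(code = codes, name = names, stringsAsFactors = FALSE),
            class = c("lulc_legend", "data.frame"))
}

#' The seven-class Amazon study legend
#'
#' The standard re-categorisation used throughout the package examples:
#' seven cover types spanning intact forests, degraded and transformed
#' covers, urban areas and water.
#'
#' @return A `lulc_legend` with codes 1-7.
#' @export
amazon_legend <- function() {
  lulc_legend(1:7, c(
    "floodplain forests",
    "Amazon forests",
    "fragmented forests and secondary vegetation",
    "grasslands and shrublands",
    "pastures and crops",
    "urban and artificialized cover",
    "water bodies and wetlands"
  ))
}

#' Read a legend from a 2-column CSV (code,name)
#' @param path file path.
#' @return A `lulc_legend`.
#' @export
read_legend <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(df)))
    stop("legend CSV must have columns 'code' and 'name'")
  lulc_legend(df$code, df$name)
}

#' Write a legend to CSV
#' @param legend a `lulc_legend`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path) {
  utils::write.csv(as.data.frame(legend), path, row.names = FALSE)
  invisible(path)
}

legend_codes <- function(legend) legend$code

#' Look up class names / codes in a legend
#' @param legend a `lulc_legend`.
#' @param code class code(s).
#' @return `legend_name`: the class name(s); `legend_code`: the class code(s).
#' @export
legend_name <- function(legend, code) {
  legend$name[match(code, legend$code)]
}

#' @rdname legend_name
#' @param name class name(s).
#' @export
legend_code <- function(legend, name) {
  i <- match(name, legend$name)
  if (anyNA(i)) stop("unknown class name(s): ", paste(name[is.na(i)], collapse = ", "))
  legend$code[i]
}

same_legend <- function(a, b) {
  identical(a$code, b$code) && identical(a$name, b$name)
}
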