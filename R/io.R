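#' Raster and report input/output
#'
#' Grids are exchanged as ESRI ASCII grid (`.asc`) files — a plain-text,
#' GIS-readable single-band raster format — with `NODATA_value` for nodata
#' cells. Zone maps carry a CSV legend sidecar (`code,standard_name`); reports
#' and generator parameters are JSON.
#'
#' @name raster-io
NULL

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric or integer matrix (row 1 = north).
#' @param path Output path.
#' @param cell_size Cell side in metres.
#' @param xllcorner,yllcorner Lower-left corner coordinates.
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cell_size, xllcorner = 0, yllcorner = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(xllcorner, scientific = FALSE)),
    paste("yllcorner", format(yllcorner, scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  ), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  utils::write.table(mm, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `values` (matrix, `NA` for nodata), `cell_size`,
#'   `xllcorner`, `yllcorner`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("malformed ASCII grid header in ", path)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body size mismatch in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, cell_size = hdr$cellsize,
       xllcorner = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
       yllcorner = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner)
}

#' Write a zone map (raster + legend sidecar)
#'
#' @param zonemap A `zone_map`.
#' @param path Output `.asc` path; the legend is written next to it as
#'   `<path>.legend.csv`.
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(zonemap, path) {
  stopifnot(inherits(zonemap, "zone_map"))
  write_ascii_grid(zonemap$labels, path, zonemap$cell_size, nodata = 0)
  legend <- data.frame(code = unname(zonemap$legend),
                       standard_name = names(zonemap$legend),
                       stringsAsFactors = FALSE)
  utils::write.csv(legend, paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}

#' Write a structured report as JSON
#'
#' Deterministic, human-readable JSON used for rule-violation and accuracy
#' reports.
#'
#' @param x A list or data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a zone map written by [write_zone_map()]
#'
#' @param path The `.asc` path.
#' @param legend_path Legend CSV path (default `<path>.legend.csv`).
#' @param cell_size Override for the cell size (default from the header).
#' @return A `zone_map` (without threshold provenance).
#' @export
read_zone_map <- function(path, legend_path = paste0(path, ".legend.csv"),
                          cell_size = NULL) {
  grid <- read_ascii_grid(path)
  leg <- utils::read.csv(legend_path, stringsAsFactors = FALSE)
  legend <- stats::setNames(as.integer(leg$code), leg$standard_name)
  labels <- matrix(as.integer(grid$values), nrow(grid$values),
                   ncol(grid$values))
  new_zone_map(labels, legend, config = NULL, scheme_version = NA_character_,
               cell_size = if (is.null(cell_size)) grid$cell_size else
                 cell_size)
}
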