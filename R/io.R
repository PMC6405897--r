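#' Read and write point patterns as CSV
#'
#' Patterns are stored as a two-column CSV with header `x,y` (coordinates in
#' window units). Generation metadata (process label, seed, window bounds and
#' topology) travels in a JSON sidecar named `<path>.json`, so the CSV stays
#' consumable by any tabular tool.
#'
#' @param pattern a [point_pattern()].
#' @param path CSV file path.
#' @return `write_pattern_csv` returns `path` invisibly; `read_pattern_csv`
#'   returns a [point_pattern()] (process `"external"` if no sidecar found).
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  write.csv(data.frame(x = pattern$x, y = pattern$y), path, row.names = FALSE)
  w <- pattern$window
  meta <- list(process = pattern$process, seed = pattern$seed,
               n = npoints(pattern),
               window = list(xmin = w$xmin, ymin = w$ymin, xmax = w$xmax,
                             ymax = w$ymax, topology = w$topology))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("x", "y") %in% names(d))) {
    frag_stop("pattern CSV must have columns x and y", "fragsim_error_io")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    w <- make_window(meta$window$xmin, meta$window$ymin, meta$window$xmax,
                     meta$window$ymax, topology = meta$window$topology)
    seed <- if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_ else meta$seed
    point_pattern(d$x, d$y, w, meta$process, seed)
  } else {
    point_pattern(d$x, d$y, unit_square("planar"), "external")
  }
}

#' Read and write habitat maps as ESRI ASCII grids
#'
#' Standard `.asc` format: a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by the cell values in
#' north-up row order; habitat cells are written as 1, matrix cells as 0.
#'
#' @param map a [habitat_map()].
#' @param path output `.asc` file path.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   [habitat_map()].
#' @export
write_asc <- function(map, path) {
  stopifnot(inherits(map, "habitat_map"))
  w <- map$window
  side <- nrow(map$grid)
  cellsize <- (w$xmax - w$xmin) / side
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", side),
               sprintf("nrows %d", side),
               sprintf("xllcorner %.10g", w$xmin),
               sprintf("yllcorner %.10g", w$ymin),
               sprintf("cellsize %.10g", cellsize),
               "NODATA_value -9999"), con)
  # north-up: first data row is the top (largest y); grid is [x, y]
  for (j in rev(seq_len(side))) {
    writeLines(paste(as.integer(map$grid[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(header, `[`, "", 1))
  vals <- as.numeric(vapply(header, `[`, "", 2))
  names(vals) <- keys
  ncols <- as.integer(vals["ncols"]); nrows <- as.integer(vals["nrows"])
  if (is.na(ncols) || is.na(nrows)) {
    frag_stop("malformed ESRI ASCII header", "fragsim_error_io")
  }
  cellsize <- unname(vals["cellsize"])
  xll <- unname(vals["xllcorner"]); yll <- unname(vals["yllcorner"])
  rows <- lapply(lines[7:(6 + nrows)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)   # m[k, ] is the k-th row from the top
  grid <- t(m[rev(seq_len(nrows)), , drop = FALSE])  # back to [x, y]
  w <- make_window(xll, yll, xll + ncols * cellsize, yll + nrows * cellsize)
  habitat_map(grid > 0, habitat_amount = mean(grid > 0), window = w)
}

#' Write disk landscapes as CSV
#'
#' One row per circular fragment with columns `cx,cy,r`.
#'
#' @param landscape a [make_disk_landscape()] object.
#' @param path output CSV path.
#' @export
write_disks_csv <- function(landscape, path) {
  stopifnot(inherits(landscape, "disk_landscape"))
  write.csv(data.frame(cx = landscape$cx, cy = landscape$cy,
                       r = landscape$radius),
            path, row.names = FALSE)
  invisible(path)
}
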