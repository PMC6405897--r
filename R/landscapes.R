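#' Fractal surface by midpoint displacement
#'
#' Classic diamond-square midpoint displacement (without random additions):
#' the four grid corners are initialized from a standard normal; at recursion
#' level `l` the diamond step sets each cell-centre to the mean of its four
#' diagonal neighbours and the square step sets each edge midpoint to the
#' mean of its (3 or 4) in-grid axial neighbours, both plus a normal
#' perturbation with standard deviation `(1/2)^(l * hurst)`. The Hurst factor
#' controls the surface roughness: `hurst` near 1 gives smooth surfaces
#' (contiguous habitat after thresholding, low fragmentation per se), `hurst`
#' near 0 gives rugged surfaces (scattered habitat, high fragmentation per
#' se). The fractal dimension is `D = 3 - hurst` by construction.
#'
#' @param hurst Hurst factor H, strictly between 0 and 1.
#' @param levels number of recursion levels; the grid has side
#'   `2^levels + 1` (default 7 gives the 129 x 129 maps of the study design).
#' @param seed integer seed.
#' @return object of class `fractal_surface`: list with the `values` matrix
#'   (first index = x cell, second = y cell), `hurst`, `levels`, `seed`.
#' @examples
#' s <- midpoint_displacement(0.5, levels = 5, seed = 1)
#' dim(s$values)  # 33 x 33
#' @export
midpoint_displacement <- function(hurst, levels = 7L, seed = NULL) {
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1) {
    frag_stop("hurst must lie strictly in (0, 1)", "fragsim_error_parameter")
  }
  if (levels < 1) frag_stop("levels must be >= 1", "fragsim_error_parameter")
  if (!is.null(seed)) set.seed(seed)
  levels <- as.integer(levels)
  v <- midpoint_displacement_cpp(hurst, levels)
  structure(list(values = v, hurst = hurst, levels = levels,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "fractal_surface")
}

#' Binary habitat map
#'
#' Container for a binary raster over a window: `TRUE` cells are habitat,
#' `FALSE` cells are hostile matrix. The grid tiles the window exactly with
#' square cells; `grid[i, j]` covers the half-open cell
#' `[(i-1)c, ic) x [(j-1)c, jc)` (in window coordinates, `c` = cell size),
#' with the `x = xmax` / `y = ymax` boundary assigned to the last cell.
#'
#' @param grid logical (or 0/1) square matrix; first index = x cell, second
#'   index = y cell.
#' @param habitat_amount nominal habitat proportion `p` recorded for the map.
#' @param window window the raster tiles (planar or toroidal; only the point
#'   containment test uses it).
#' @return object of class `habitat_map`.
#' @export
habitat_map <- function(grid, habitat_amount = mean(grid), window = unit_square()) {
  grid <- matrix(as.logical(grid), nrow(grid), ncol(grid))
  if (nrow(grid) != ncol(grid)) {
    frag_stop("habitat grid must be square", "fragsim_error_parameter")
  }
  structure(list(grid = grid, habitat_amount = habitat_amount,
                 window = window),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat map: %d x %d cells, %d habitat (p = %.4g)\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid), x$habitat_amount))
  invisible(x)
}

#' Threshold a fractal surface into a habitat map
#'
#' Habitat is assigned by rank rather than by a fixed elevation: exactly
#' `k = round_half_up(p * n_cells)` cells with the highest surface values
#' become habitat, so the realized habitat amount is exact for every map.
#' Ties at the cut value (measure-zero for continuous surfaces) are broken
#' uniformly at random using `tie_seed`.
#'
#' @param surface a [midpoint_displacement()] surface.
#' @param habitat_amount habitat proportion `p` in \[0, 1\].
#' @param tie_seed seed for random tie-breaking (and nothing else).
#' @param window window the map tiles.
#' @return a [habitat_map()] with exactly `round_half_up(p * n_cells)`
#'   habitat cells.
#' @examples
#' s <- midpoint_displacement(0.5, levels = 7, seed = 1)
#' m <- threshold_to_habitat(s, 0.2)
#' sum(m$grid)  # 3328 of 16641 cells
#' @export
threshold_to_habitat <- function(surface, habitat_amount, tie_seed = NULL,
                                 window = unit_square()) {
  stopifnot(inherits(surface, "fractal_surface"))
  if (is.na(habitat_amount) || habitat_amount < 0 || habitat_amount > 1) {
    frag_stop("habitat_amount must lie in [0, 1]", "fragsim_error_parameter")
  }
  vals <- surface$values
  n_cells <- length(vals)
  k <- round_half_up(habitat_amount * n_cells)
  sel <- logical(n_cells)
  if (k > 0) {
    v <- as.vector(vals)
    kth <- -sort(-v, partial = k)[k]   # k-th largest value (the cut)
    sel <- v > kth
    need <- k - sum(sel)
    if (need > 0) {                    # ties at the cut: sample uniformly
      ties <- which(v == kth)
      if (!is.null(tie_seed)) set.seed(tie_seed)
      sel[ties[sample.int(length(ties), need)]] <- TRUE
    }
  }
  habitat_map(matrix(sel, nrow(vals), ncol(vals)), habitat_amount, window)
}

#' Boolean landscape of equal-radius circular fragments
#'
#' `n_disks` fragment centres are placed uniformly in the (toroidal) window
#' and all fragments share the radius `R` solving
#' `n_disks * pi * R^2 = p * A`, so the *nominal* habitat amount is `p`.
#' Overlaps are permitted (the Boolean-model assumption under which the
#' analytical survival solution is tractable), so the realized covered
#' fraction can fall below `p`; [realized_coverage()] reports it.
#'
#' @param n_disks number of circular fragments (>= 1).
#' @param habitat_amount nominal habitat proportion `p` in (0, 1).
#' @param window observation window.
#' @param seed integer seed.
#' @return object of class `disk_landscape`: centre coordinates `cx`, `cy`,
#'   common `radius`, `habitat_amount`, `window`.
#' @examples
#' dl <- make_disk_landscape(4, 0.25, seed = 1)
#' dl$radius  # sqrt(0.25 / (4 * pi)) ~ 0.141
#' @export
make_disk_landscape <- function(n_disks, habitat_amount,
                                window = unit_square(), seed = NULL) {
  if (n_disks < 1) frag_stop("n_disks must be >= 1", "fragsim_error_parameter")
  if (is.na(habitat_amount) || habitat_amount <= 0 || habitat_amount >= 1) {
    frag_stop("habitat_amount must lie in (0, 1)", "fragsim_error_parameter")
  }
  A <- window_area(window)
  R <- sqrt(habitat_amount * A / (n_disks * pi))
  if (2 * R > min(window_sides(window))) {
    frag_stop("fragment diameter exceeds the window side",
              "fragsim_error_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  structure(list(cx = runif(n_disks, window$xmin, window$xmax),
                 cy = runif(n_disks, window$ymin, window$ymax),
                 radius = R, habitat_amount = habitat_amount,
                 window = window,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "disk_landscape")
}

#' @export
print.disk_landscape <- function(x, ...) {
  cat(sprintf("disk landscape: %d fragments, radius %.4g (nominal p = %.4g)\n",
              length(x$cx), x$radius, x$habitat_amount))
  invisible(x)
}

#' Realized covered fraction of a disk landscape
#'
#' Fraction of the window actually covered by the union of fragments,
#' estimated on a fine grid of cell centres (overlaps make it fall below the
#' nominal habitat amount).
#'
#' @param landscape a [make_disk_landscape()] object.
#' @param grid_n grid resolution per side.
#' @export
realized_coverage <- function(landscape, grid_n = 512L) {
  stopifnot(inherits(landscape, "disk_landscape"))
  w <- landscape$window
  s <- window_sides(w)
  gx <- w$xmin + (seq_len(grid_n) - 0.5) / grid_n * s[1]
  gy <- w$ymin + (seq_len(grid_n) - 0.5) / grid_n * s[2]
  covered <- matrix(FALSE, grid_n, grid_n)
  for (k in seq_along(landscape$cx)) {
    dx <- abs(gx - landscape$cx[k]); dx <- pmin(dx, s[1] - dx)
    dy <- abs(gy - landscape$cy[k]); dy <- pmin(dy, s[2] - dy)
    covered <- covered | (outer(dx^2, dy^2, "+") <= landscape$radius^2)
  }
  mean(covered)
}

#' Point-in-habitat query
#'
#' Is the location `(x, y)` inside habitat? For rasters the containing cell
#' is looked up with half-open cells and the `x = xmax` / `y = ymax`
#' boundaries assigned to the last cell; for disk landscapes the toroidal
#' distance to the nearest fragment centre is compared with the radius.
#' Vectorized over coordinates.
#'
#' @param map a [habitat_map()] or [make_disk_landscape()] object.
#' @param x,y point coordinates (must lie inside the map's window).
#' @return logical vector.
#' @export
is_habitat <- function(map, x, y) UseMethod("is_habitat")

#' @export
is_habitat.habitat_map <- function(map, x, y) {
  w <- map$window
  if (length(x) && !all(points_inside(x, y, w))) {
    frag_stop("point outside the window", "fragsim_error_window")
  }
  side <- nrow(map$grid)
  s <- window_sides(w)
  ix <- pmin(floor((x - w$xmin) / s[1] * side), side - 1)
  iy <- pmin(floor((y - w$ymin) / s[2] * side), side - 1)
  map$grid[cbind(ix + 1, iy + 1)]
}

#' @export
is_habitat.disk_landscape <- function(map, x, y) {
  w <- map$window
  if (length(x) && !all(points_inside(x, y, w))) {
    frag_stop("point outside the window", "fragsim_error_window")
  }
  s <- window_sides(w)
  out <- rep(FALSE, length(x))
  for (k in seq_along(map$cx)) {
    dx <- abs(x - map$cx[k])
    dy <- abs(y - map$cy[k])
    if (w$topology == "toroidal") {
      dx <- pmin(dx, s[1] - dx); dy <- pmin(dy, s[2] - dy)
    }
    out <- out | (dx^2 + dy^2 <= map$radius^2)
  }
  out
}

#' Count habitat patches
#'
#' Number of connected habitat patches under rook (4-neighbour) adjacency,
#' computed as the number of connected components of the habitat-cell
#' adjacency graph. This is the single landscape metric needed to verify
#' that low Hurst factors produce many scattered fragments and high Hurst
#' factors few contiguous ones.
#'
#' @param map a [habitat_map()].
#' @param toroidal treat the raster edges as wrapping (default `FALSE`,
#'   matching the visual interpretation of the maps).
#' @return integer patch count.
#' @export
count_patches <- function(map, toroidal = FALSE) {
  stopifnot(inherits(map, "habitat_map"))
  g <- map$grid
  n <- nrow(g)
  idx <- matrix(seq_len(n * n), n, n)
  hcells <- which(g)
  if (!length(hcells)) return(0L)
  right <- cbind(as.vector(idx[-n, ]), as.vector(idx[-1, ]))
  up <- cbind(as.vector(idx[, -n]), as.vector(idx[, -1]))
  edges <- rbind(right, up)
  if (toroidal) {
    edges <- rbind(edges,
                   cbind(idx[n, ], idx[1, ]),
                   cbind(idx[, n], idx[, 1]))
  }
  keep <- g[edges[, 1]] & g[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  relabel <- integer(n * n)
  relabel[hcells] <- seq_along(hcells)
  gr <- igraph::make_graph(t(cbind(relabel[edges[, 1]], relabel[edges[, 2]])),
                           n = length(hcells), directed = FALSE)
  igraph::count_components(gr)
}
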