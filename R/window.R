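#' Rectangular observation window
#'
#' The arena in which point patterns live and which habitat maps tile. The
#' default study arena is the unit square. The window topology controls the
#' distance metric used by diagnostics ([nn_distances()], [pair_count()]) and
#' by the Strauss sampler: `"toroidal"` wraps opposite edges (periodic
#' boundary, the default for internally generated patterns, so intensity is
#' spatially uniform), `"planar"` uses the ordinary Euclidean metric
#' (appropriate for externally observed patterns).
#'
#' @param xmin,ymin,xmax,ymax window bounds (dimensionless landscape units).
#' @param topology `"toroidal"` or `"planar"`.
#' @return An object of class `frag_window`.
#' @examples
#' w <- make_window()          # unit square, toroidal
#' window_area(w)
#' @export
make_window <- function(xmin = 0, ymin = 0, xmax = 1, ymax = 1,
                        topology = c("toroidal", "planar")) {
  topology <- match.arg(topology)
  if (!(xmax > xmin) || !(ymax > ymin)) {
    frag_stop("window must have xmax > xmin and ymax > ymin",
              "fragsim_error_window")
  }
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                 topology = topology),
            class = "frag_window")
}

#' @rdname make_window
#' @export
unit_square <- function(topology = c("toroidal", "planar")) {
  make_window(0, 0, 1, 1, topology = match.arg(topology))
}

#' @rdname make_window
#' @param w a `frag_window`.
#' @export
window_area <- function(w) (w$xmax - w$xmin) * (w$ymax - w$ymin)

window_sides <- function(w) c(w$xmax - w$xmin, w$ymax - w$ymin)

same_window <- function(a, b, tol = 1e-12) {
  all(abs(c(a$xmin - b$xmin, a$ymin - b$ymin,
            a$xmax - b$xmax, a$ymax - b$ymax)) < tol)
}

#' @export
print.frag_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g] (%s)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$topology))
  invisible(x)
}

# wrap coordinates into the window (toroidal reduction)
wrap_into <- function(x, lo, hi) lo + (x - lo) %% (hi - lo)

points_inside <- function(x, y, w) {
  x >= w$xmin & x <= w$xmax & y >= w$ymin & y <= w$ymax
}

# full pairwise distance matrix honouring window topology
pairwise_distances <- function(x, y, w) {
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  if (w$topology == "toroidal") {
    s <- window_sides(w)
    dx <- pmin(dx, s[1] - dx)
    dy <- pmin(dy, s[2] - dy)
  }
  sqrt(dx^2 + dy^2)
}
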