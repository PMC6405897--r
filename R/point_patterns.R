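#' Point pattern container
#'
#' A finite set of individual coordinates inside a window, with the generating
#' process recorded. Every point represents one individual of the focal
#' species prior to habitat conversion.
#'
#' @param x,y numeric coordinate vectors of equal length.
#' @param window a [make_window()] object; defaults to the toroidal unit
#'   square.
#' @param process label of the generating process: one of `"csr"`, `"thomas"`,
#'   `"strauss"`, `"external"`.
#' @param seed the seed used to generate the pattern, or `NA` for external
#'   data.
#' @return An object of class `point_pattern` with fields `x`, `y`, `window`,
#'   `process`, `seed`.
#' @export
point_pattern <- function(x, y, window = unit_square(),
                          process = c("external", "csr", "thomas", "strauss"),
                          seed = NA_integer_) {
  process <- match.arg(process)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    frag_stop("x and y must have equal length", "fragsim_error_parameter")
  }
  if (length(x) && !all(points_inside(x, y, window))) {
    frag_stop("all points must lie inside the window", "fragsim_error_window")
  }
  structure(list(x = x, y = y, window = window, process = process,
                 seed = seed),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param pattern a [point_pattern()].
#' @export
npoints <- function(pattern) length(pattern$x)

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points (%s)\n", npoints(x), x$process))
  print(x$window)
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ...) {
  plot(x$x, x$y, xlim = c(x$window$xmin, x$window$xmax),
       ylim = c(x$window$ymin, x$window$ymax), asp = 1,
       xlab = "x", ylab = "y", pch = 16, cex = 0.6, ...)
  invisible(x)
}

#' Simulate complete spatial randomness (CSR)
#'
#' Homogeneous binomial/Poisson process conditioned on `n` points: each
#' individual is placed independently and uniformly in the window. This is
#' the random species distribution of the study design, simulated at
#' densities of 10, 100 and 1000 individuals per unit square.
#'
#' @param n number of individuals (>= 0).
#' @param window observation window.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return a [point_pattern()] with exactly `n` points.
#' @examples
#' p <- simulate_csr(100, seed = 1)
#' npoints(p)
#' @export
simulate_csr <- function(n, window = unit_square(), seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 0) {
    frag_stop("n must be a single non-negative count", "fragsim_error_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, window$xmin, window$xmax)
  y <- runif(n, window$ymin, window$ymax)
  point_pattern(x, y, window, "csr", if (is.null(seed)) NA_integer_ else seed)
}

#' Thomas cluster process parameters
#'
#' The aggregated species distribution: cluster centres follow CSR with
#' intensity `rho`, each centre receives offspring (mean `mu` per cluster),
#' and offspring are displaced from their centre by an isotropic bivariate
#' Gaussian with per-axis standard deviation `sigma`. The expected total
#' abundance is `n_P = rho * A * mu` with `n_C = rho * A` clusters.
#'
#' Two sampling modes are provided. In `"conditioned"` mode (default) the
#' number of centres is exactly `n_clusters` and exactly `n_points` offspring
#' are allocated to centres by an equal-probability multinomial, so every
#' replicate has the same total abundance. In `"poisson"` mode the centre
#' count is Poisson(`rho * A`) and per-cluster offspring counts are
#' Poisson(`mu`); this is the textbook Thomas process assumed by the
#' analytical survival solution ([survival_thomas_disks()]).
#'
#' @param n_points total abundance n_P (expected abundance in poisson mode).
#' @param n_clusters number of clusters n_C (expected number in poisson mode).
#' @param sigma cluster spread: per-axis standard deviation of the Gaussian
#'   offspring displacement, in window units.
#' @param mode `"conditioned"` or `"poisson"`.
#' @return an object of class `thomas_params` with derived fields `mu`
#'   (points per cluster) and, given a window, intensity `rho = n_C / A`.
#' @export
thomas_params <- function(n_points, n_clusters, sigma,
                          mode = c("conditioned", "poisson")) {
  mode <- match.arg(mode)
  if (n_points < 0 || n_clusters < 1) {
    frag_stop("need n_points >= 0 and n_clusters >= 1",
              "fragsim_error_parameter")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    frag_stop("sigma must be > 0", "fragsim_error_parameter")
  }
  structure(list(n_points = n_points, n_clusters = n_clusters,
                 sigma = sigma, mode = mode, mu = n_points / n_clusters),
            class = "thomas_params")
}

#' Simulate the Thomas cluster process
#'
#' Cluster centres are uniform in the window; offspring are displaced by
#' independent Gaussian offsets (per-axis sd `sigma`) and wrapped toroidally
#' into the window, which keeps the intensity spatially uniform (rejection
#' would thin clusters near the boundary).
#'
#' @param params a [thomas_params()] object.
#' @param window observation window.
#' @param seed integer seed.
#' @return a [point_pattern()]; in conditioned mode its abundance is exactly
#'   `params$n_points`.
#' @examples
#' pat <- simulate_thomas(thomas_params(100, 5, 0.02), seed = 1)
#' npoints(pat)  # exactly 100
#' @export
simulate_thomas <- function(params, window = unit_square(), seed = NULL) {
  stopifnot(inherits(params, "thomas_params"))
  if (!is.null(seed)) set.seed(seed)
  A <- window_area(window)
  rho <- params$n_clusters / A
  if (params$mode == "conditioned") {
    n_c <- params$n_clusters
  } else {
    n_c <- rpois(1, rho * A)
  }
  if (n_c == 0) {
    return(point_pattern(numeric(0), numeric(0), window, "thomas",
                         if (is.null(seed)) NA_integer_ else seed))
  }
  cx <- runif(n_c, window$xmin, window$xmax)
  cy <- runif(n_c, window$ymin, window$ymax)
  if (params$mode == "conditioned") {
    parent <- sample.int(n_c, params$n_points, replace = TRUE)
  } else {
    counts <- rpois(n_c, params$mu)
    parent <- rep(seq_len(n_c), counts)
  }
  x <- wrap_into(cx[parent] + rnorm(length(parent), 0, params$sigma),
                 window$xmin, window$xmax)
  y <- wrap_into(cy[parent] + rnorm(length(parent), 0, params$sigma),
                 window$ymin, window$ymax)
  point_pattern(x, y, window, "thomas",
                if (is.null(seed)) NA_integer_ else seed)
}

#' Strauss process parameters
#'
#' The regular (inhibited) species distribution: a Gibbs point process with
#' unnormalized density proportional to `gamma^s(x)`, where `s(x)` counts the
#' unordered point pairs closer than the interaction radius `r`. `gamma = 1`
#' is CSR; `gamma = 0` is a hard-core process with no pair closer than `r`.
#' The default interaction radius is \code{r = 1/sqrt(n_points)}, the spacing of a
#' perfect lattice of `n_points` individuals covering the unit landscape.
#'
#' @param n_points fixed number of individuals N.
#' @param gamma inhibition strength in \[0, 1\].
#' @param r interaction radius (window units); default `1/sqrt(n_points)`.
#' @param n_sweeps total number of single-point Metropolis-Hastings updates.
#' @param burn_in updates discarded before recording diagnostics.
#' @return an object of class `strauss_params`.
#' @export
strauss_params <- function(n_points, gamma, r = 1 / sqrt(n_points),
                           n_sweeps = 1e5, burn_in = n_sweeps / 2) {
  if (n_points < 0) frag_stop("n_points must be >= 0", "fragsim_error_parameter")
  if (is.na(gamma) || gamma < 0 || gamma > 1) {
    frag_stop("gamma must lie in [0, 1]", "fragsim_error_parameter")
  }
  if (!is.finite(r) || r <= 0) frag_stop("r must be > 0", "fragsim_error_parameter")
  if (!(n_sweeps > burn_in) || burn_in < 0) {
    frag_stop("need n_sweeps > burn_in >= 0", "fragsim_error_parameter")
  }
  structure(list(n_points = n_points, gamma = gamma, r = r,
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in)),
            class = "strauss_params")
}

# Feasible starting configurations for the hard-core case (gamma = 0).
#
# The default interaction radius r = 1/sqrt(N) implies a packing fraction of
# pi/4 ~ 0.785, beyond the jamming density of random sequential adsorption
# (~0.547), so dart throwing alone cannot initialize the chain at the design
# densities. When N is a sum of two squares a^2 + b^2, the scaled-rotated
# integer lattice (1/N)*{(a*x - b*y, b*x + a*y)} contains Z^2, so it wraps
# exactly onto the unit torus with N distinct points whose minimum spacing is
# exactly 1/sqrt(N) = r. This covers N in {2, 10, 100, 1000, ...}; other
# combinations fall back to dart throwing (adequate for sub-jamming custom r)
# and finally raise a feasibility error.
two_squares_decomposition <- function(n) {
  a <- 0:floor(sqrt(n))
  b2 <- n - a^2
  b <- sqrt(b2)
  ok <- which(abs(b - round(b)) < 1e-9)
  if (!length(ok)) return(NULL)
  c(a[ok[length(ok)]], round(b[ok[length(ok)]]))
}

.lattice_cache <- new.env(parent = emptyenv())

gauss_lattice_points <- function(n, ab) {
  key <- paste(n, ab[1], ab[2])
  if (!is.null(.lattice_cache[[key]])) return(.lattice_cache[[key]])
  a <- ab[1]; b <- ab[2]
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  u <- (a * xy$x - b * xy$y) %% n
  v <- (b * xy$x + a * xy$y) %% n
  keep <- !duplicated(u * n + v)
  out <- list(x = u[keep] / n, y = v[keep] / n)
  .lattice_cache[[key]] <- out
  out
}

hardcore_init <- function(n, r, window, max_attempts = 400L * n) {
  s <- window_sides(window)
  # exact lattice start for the unit-square torus at the default radius
  if (window$topology == "toroidal" &&
      isTRUE(all.equal(s[1], s[2])) && r <= s[1] / sqrt(n) + 1e-12) {
    ab <- two_squares_decomposition(n)
    if (!is.null(ab)) {
      g <- gauss_lattice_points(n, ab)
      stopifnot(length(g$x) == n)
      return(list(x = window$xmin + g$x * s[1],
                  y = window$ymin + g$y * s[2]))
    }
  }
  # random sequential adsorption with bounded attempts
  x <- numeric(n); y <- numeric(n)
  placed <- 0L; attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    px <- runif(1, window$xmin, window$xmax)
    py <- runif(1, window$ymin, window$ymax)
    ok <- TRUE
    if (placed > 0L) {
      dx <- abs(x[seq_len(placed)] - px)
      dy <- abs(y[seq_len(placed)] - py)
      if (window$topology == "toroidal") {
        dx <- pmin(dx, s[1] - dx); dy <- pmin(dy, s[2] - dy)
      }
      ok <- all(dx * dx + dy * dy >= r * r)
    }
    if (ok) {
      placed <- placed + 1L
      x[placed] <- px; y[placed] <- py
    }
  }
  if (placed == n) return(list(x = x, y = y))
  frag_stop(sprintf(
    "no feasible hard-core configuration found for n = %d, r = %g", n, r),
    "fragsim_error_feasibility")
}

#' Simulate the Strauss process by Metropolis-Hastings
#'
#' Fixed-n single-point-displacement Metropolis-Hastings sampler for the
#' Strauss density. Each update picks a random individual and proposes, with
#' probability 1/2, a fresh uniform location (global move, mixes across
#' gaps), otherwise a Gaussian jitter with scale `r/2` (local move). The
#' acceptance ratio is `gamma^(s_new - s_old)` with the `gamma = 0`
#' convention `0^0 = 1`, so hard-core moves are accepted iff they keep
#' `s = 0`. For `gamma = 0` the chain starts from a feasible configuration
#' (dart throwing, then a triangular torus lattice); otherwise from CSR.
#'
#' @param params a [strauss_params()] object.
#' @param window observation window.
#' @param seed integer seed.
#' @param return_trace if `TRUE`, attach the trace of the pair statistic
#'   `s(x)` recorded after every post-burn-in update (used for validating the
#'   sampler against exact small-state distributions).
#' @return a [point_pattern()] with exactly `params$n_points` points; with
#'   `return_trace = TRUE` the integer vector of `s` values is attached as
#'   attribute `"s_trace"`.
#' @examples
#' pat <- simulate_strauss(strauss_params(50, gamma = 0), seed = 1)
#' pair_count(pat, 1 / sqrt(50))  # 0: perfect inhibition
#' @export
simulate_strauss <- function(params, window = unit_square(), seed = NULL,
                             return_trace = FALSE) {
  stopifnot(inherits(params, "strauss_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_points
  if (n == 0) {
    return(point_pattern(numeric(0), numeric(0), window, "strauss",
                         if (is.null(seed)) NA_integer_ else seed))
  }
  if (params$gamma == 0) {
    init <- hardcore_init(n, params$r, window)
  } else {
    init <- list(x = runif(n, window$xmin, window$xmax),
                 y = runif(n, window$ymin, window$ymax))
  }
  res <- strauss_mh_cpp(init$x - window$xmin, init$y - window$ymin,
                        params$gamma, params$r,
                        params$n_sweeps, params$burn_in,
                        isTRUE(return_trace),
                        window$xmax - window$xmin,
                        window$ymax - window$ymin,
                        window$topology == "toroidal",
                        params$r / 2)
  out <- point_pattern(res$x + window$xmin, res$y + window$ymin, window,
                       "strauss", if (is.null(seed)) NA_integer_ else seed)
  if (isTRUE(return_trace)) attr(out, "s_trace") <- res$s_trace
  out
}

#' Nearest-neighbour distances
#'
#' Distance from each point to its nearest neighbour, honouring the window
#' topology (toroidal windows wrap around the edges).
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @return numeric vector of length `npoints(pattern)`.
#' @export
nn_distances <- function(pattern) {
  n <- npoints(pattern)
  if (n < 2) {
    frag_stop("nearest-neighbour distances need at least 2 points",
              "fragsim_error_diagnostic")
  }
  d <- pairwise_distances(pattern$x, pattern$y, pattern$window)
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Count close point pairs
#'
#' Number of unordered point pairs at distance strictly less than `r` — the
#' Strauss sufficient statistic `s(x)` — honouring the window topology.
#'
#' Pairs are "close" when their distance is strictly below `r`; distances
#' within a relative 1e-12 of `r` are treated as equal to `r` (hence not
#' close). The same convention is used inside the Strauss sampler, so
#' hard-core lattice configurations with spacing exactly `r` have `s = 0`
#' under floating-point arithmetic. Ties are measure-zero for continuous
#' patterns, so this convention never affects them.
#'
#' @param pattern a [point_pattern()].
#' @param r pair distance threshold (> 0).
#' @return integer count.
#' @export
pair_count <- function(pattern, r) {
  if (!is.finite(r) || r <= 0) frag_stop("r must be > 0", "fragsim_error_parameter")
  n <- npoints(pattern)
  if (n < 2) return(0L)
  d <- pairwise_distances(pattern$x, pattern$y, pattern$window)
  as.integer(sum(d[upper.tri(d)] < r * (1 - 1e-12)))
}
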