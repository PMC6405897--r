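#' Closed-form survival probability under complete spatial randomness
#'
#' With `n` independently, uniformly placed individuals and habitat fraction
#' `p`, each individual survives independently with probability `p`, so the
#' species survives (at least one individual in habitat) with probability
#' `1 - (1 - p)^n` — independent of fragmentation per se. This is the null
#' model against which geometric fragmentation effects are measured.
#'
#' @param n initial abundance (>= 0); vectorized.
#' @param habitat_amount habitat proportion p in \[0, 1\]; vectorized.
#' @return survival probability in \[0, 1\].
#' @examples
#' survival_csr(10, 0.05)  # 0.401263
#' @export
survival_csr <- function(n, habitat_amount) {
  if (any(n < 0) || any(habitat_amount < 0 | habitat_amount > 1)) {
    frag_stop("need n >= 0 and habitat_amount in [0, 1]",
              "fragsim_error_parameter")
  }
  1 - (1 - habitat_amount)^n
}

#' Gaussian mass over a disk
#'
#' Probability that a point displaced from a cluster centre by an isotropic
#' bivariate Gaussian (per-axis standard deviation `sigma`) lands inside a
#' disk of radius `radius` whose centre lies at distance `d` from the
#' cluster centre. The squared displacement-to-disk-centre distance is
#' `sigma^2` times a noncentral chi-square with 2 degrees of freedom and
#' noncentrality `(d/sigma)^2`, so the mass is exact:
#' `pchisq((radius/sigma)^2, df = 2, ncp = (d/sigma)^2)` (equivalently
#' `1 - Q_1(d/sigma, radius/sigma)` with the Marcum Q-function).
#'
#' @param d distance between cluster centre and disk centre (>= 0).
#' @param sigma per-axis standard deviation of the displacement (> 0).
#' @param radius disk radius (> 0).
#' @return probability; vectorized over `d`.
#' @examples
#' gaussian_disk_mass(0, 0.05, 0.1)  # 1 - exp(-0.1^2 / (2 * 0.05^2))
#' @export
gaussian_disk_mass <- function(d, sigma, radius) {
  if (any(d < 0) || sigma <= 0 || radius <= 0) {
    frag_stop("need d >= 0, sigma > 0, radius > 0", "fragsim_error_parameter")
  }
  pchisq((radius / sigma)^2, df = 2, ncp = (d / sigma)^2)
}

#' Analytic Thomas-process survival specification
#'
#' Parameters of the Poisson-mode Thomas process (cluster-centre intensity
#' `rho`, mean `mu` offspring per cluster, offspring spread `sigma`) together
#' with the Boolean disk landscape (`n_disks` equal-radius fragments at
#' nominal habitat amount `habitat_amount`, centres uniform on the torus).
#'
#' @param rho cluster-centre intensity per unit area (> 0).
#' @param mu mean individuals per cluster (> 0).
#' @param sigma per-axis Gaussian offspring spread (> 0).
#' @param n_disks number of circular fragments (>= 1).
#' @param habitat_amount nominal covered proportion p in (0, 1).
#' @param window observation window (toroidal unit square by default).
#' @return object of class `analytic_thomas_spec`.
#' @export
analytic_thomas_spec <- function(rho, mu, sigma, n_disks, habitat_amount,
                                 window = unit_square()) {
  if (any(c(rho, mu, sigma) <= 0)) {
    frag_stop("rho, mu and sigma must all be > 0", "fragsim_error_parameter")
  }
  if (n_disks < 1 || habitat_amount <= 0 || habitat_amount >= 1) {
    frag_stop("need n_disks >= 1 and habitat_amount in (0, 1)",
              "fragsim_error_parameter")
  }
  A <- window_area(window)
  radius <- sqrt(habitat_amount * A / (n_disks * pi))
  structure(list(rho = rho, mu = mu, sigma = sigma,
                 n_disks = as.integer(n_disks),
                 habitat_amount = habitat_amount, radius = radius,
                 window = window),
            class = "analytic_thomas_spec")
}

# 1-D wrapped-Gaussian weights on an N-point torus grid, normalized later
wrapped_gauss_1d <- function(N, sigma, side = 1) {
  i <- 0:(N - 1)
  dx <- ifelse(i < N / 2, i, i - N) / N * side
  K <- max(1L, ceiling(6 * sigma / side))
  w <- numeric(N)
  for (k in -K:K) w <- w + exp(-((dx + k * side)^2) / (2 * sigma^2))
  w
}

# coverage fraction per grid cell of the union of disks, with supersampling
disk_coverage_grid <- function(cx, cy, radius, window, grid_n, supersample = 2L) {
  s <- window_sides(window)
  M <- grid_n * supersample
  gx <- (seq_len(M) - 0.5) / M * s[1]
  gy <- (seq_len(M) - 0.5) / M * s[2]
  covered <- matrix(FALSE, M, M)
  for (k in seq_along(cx)) {
    dx <- abs(gx - (cx[k] - window$xmin)); dx <- pmin(dx, s[1] - dx)
    dy <- abs(gy - (cy[k] - window$ymin)); dy <- pmin(dy, s[2] - dy)
    ix <- which(dx <= radius); iy <- which(dy <= radius)
    if (length(ix) && length(iy)) {
      covered[ix, iy] <- covered[ix, iy] |
        (outer(dx[ix]^2, dy[iy]^2, "+") <= radius^2)
    }
  }
  if (supersample == 1L) return(covered + 0)
  # average supersample x supersample blocks into coverage fractions
  sub <- matrix(0, grid_n, grid_n)
  for (a in seq_len(supersample)) {
    for (b in seq_len(supersample)) {
      sub <- sub + covered[seq(a, M, by = supersample),
                           seq(b, M, by = supersample)]
    }
  }
  sub / supersample^2
}

# q(c) = P(one offspring of a cluster centred at c lands in the habitat
# union W), for every c on the grid: circular convolution of the coverage
# indicator with the wrapped Gaussian kernel, computed by 2-D FFT on the
# torus (periodic boundaries are exact there).
offspring_habitat_prob_grid <- function(coverage, sigma, window) {
  N <- nrow(coverage)
  s <- window_sides(window)
  kern <- outer(wrapped_gauss_1d(N, sigma, s[1]),
                wrapped_gauss_1d(N, sigma, s[2]))
  kern <- kern / sum(kern)   # discrete kernel mass 1 <=> density integral 1
  q <- Re(stats::fft(stats::fft(coverage) * stats::fft(kern), inverse = TRUE)) / N^2
  pmin(pmax(q, 0), 1)
}

#' Analytic survival probability of the Thomas process on circular fragments
#'
#' Survival probability (= 1 - void probability of the habitat region) of
#' the Poisson-mode Thomas process on a Boolean landscape of equal-radius
#' disks. Conditional on a fragment configuration W, the void probability
#' follows from the generating functional of the Poisson cluster process:
#'
#'   P(void) = exp( -rho * integral over the torus of
#'                   \[1 - exp(-mu * q(c, W))\] dc )
#'
#' where `q(c, W)` is the probability that one offspring of a cluster
#' centred at `c` falls in W. `q` is evaluated on a regular torus grid by
#' FFT convolution of the (supersampled) disk-coverage indicator with the
#' wrapped Gaussian kernel; for non-overlapping configurations this equals
#' the sum of exact [gaussian_disk_mass()] terms, and for overlapping disks
#' it integrates over the union without inclusion-exclusion error. The outer
#' average over random fragment placements is Monte-Carlo over centre draws,
#' with a reported standard error.
#'
#' @param spec an [analytic_thomas_spec()].
#' @param n_landscapes Monte-Carlo draws of fragment configurations.
#' @param grid_n torus grid resolution per side for the inner integral.
#' @param supersample supersampling factor for rasterizing disk coverage.
#' @param seed integer seed for the landscape draws.
#' @return object of class `analytic_survival`: `survival` (mean over
#'   configurations), `se` (Monte-Carlo standard error), `per_landscape`
#'   (vector of conditional survival probabilities).
#' @examples
#' spec <- analytic_thomas_spec(rho = 5, mu = 20, sigma = 0.02,
#'                              n_disks = 4, habitat_amount = 0.2)
#' survival_thomas_disks(spec, n_landscapes = 20, seed = 1)$survival
#' @export
survival_thomas_disks <- function(spec, n_landscapes = 200L, grid_n = 512L,
                                  supersample = 2L, seed = NULL) {
  stopifnot(inherits(spec, "analytic_thomas_spec"))
  if (!is.null(seed)) set.seed(seed)
  w <- spec$window
  A <- window_area(w)
  vals <- numeric(n_landscapes)
  for (i in seq_len(n_landscapes)) {
    cx <- runif(spec$n_disks, w$xmin, w$xmax)
    cy <- runif(spec$n_disks, w$ymin, w$ymax)
    cov <- disk_coverage_grid(cx, cy, spec$radius, w, grid_n, supersample)
    q <- offspring_habitat_prob_grid(cov, spec$sigma, w)
    inner <- mean(1 - exp(-spec$mu * q)) * A
    if (!is.finite(inner)) {
      frag_stop("inner integral did not evaluate to a finite value",
                "fragsim_error_numeric")
    }
    vals[i] <- 1 - exp(-spec$rho * inner)
  }
  structure(list(survival = mean(vals),
                 se = sd(vals) / sqrt(n_landscapes),
                 per_landscape = vals,
                 n_landscapes = n_landscapes, grid_n = grid_n),
            class = "analytic_survival")
}

#' @export
print.analytic_survival <- function(x, ...) {
  cat(sprintf("analytic survival: %.4f (MC se %.4f over %d fragment configurations)\n",
              x$survival, x$se, x$n_landscapes))
  invisible(x)
}
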