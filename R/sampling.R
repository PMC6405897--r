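#' Cookie-cutter overlay of a species pattern on a habitat map
#'
#' All individuals located in habitat are labelled survivors; all individuals
#' in the matrix are removed. This is the pure spatial sampling process that
#' defines geometric fragmentation effects: no demography is involved, and
#' landscape-scale survival means at least one individual falls in habitat.
#'
#' @param pattern a [point_pattern()].
#' @param map a [habitat_map()] or [make_disk_landscape()] object whose
#'   window matches the pattern's.
#' @return object of class `overlay_result`: `survivors` (a
#'   [point_pattern()]), `abundance` (count of survivors) and `survived`
#'   (`abundance > 0`). The input pattern is not modified.
#' @examples
#' pat <- simulate_csr(100, seed = 1)
#' map <- threshold_to_habitat(midpoint_displacement(0.5, seed = 2), 0.2)
#' overlay(pat, map)$abundance
#' @export
overlay <- function(pattern, map) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!same_window(pattern$window, map$window)) {
    frag_stop("pattern and map have incompatible windows",
              "fragsim_error_geometry")
  }
  keep <- if (npoints(pattern)) is_habitat(map, pattern$x, pattern$y) else logical(0)
  survivors <- point_pattern(pattern$x[keep], pattern$y[keep],
                             pattern$window, pattern$process, pattern$seed)
  structure(list(survivors = survivors,
                 abundance = as.integer(sum(keep)),
                 survived = sum(keep) > 0),
            class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("overlay: %d survivors (%s)\n", x$abundance,
              if (x$survived) "survived" else "extinct"))
  invisible(x)
}

#' Species and landscape scenario specifications
#'
#' Light-weight specifications consumed by [estimate_survival()] and the
#' experiment runner. A species spec names the point process and its
#' parameters; a landscape spec names the landscape generator (`"fractal"`
#' maps from [midpoint_displacement()] + [threshold_to_habitat()], or
#' `"disks"` from [make_disk_landscape()]) and its parameters.
#'
#' @param process `"csr"`, `"thomas"` or `"strauss"`.
#' @param n_points abundance prior to fragmentation (n_P).
#' @param n_clusters,sigma,mode Thomas parameters (see [thomas_params()]).
#' @param gamma,r,n_sweeps,burn_in Strauss parameters (see
#'   [strauss_params()]); `r` defaults to `1/sqrt(n_points)`.
#' @return a classed list.
#' @export
species_spec <- function(process = c("csr", "thomas", "strauss"), n_points,
                         n_clusters = NULL, sigma = NULL,
                         mode = "conditioned",
                         gamma = NULL, r = NULL,
                         n_sweeps = 1e5, burn_in = n_sweeps / 2) {
  process <- match.arg(process)
  spec <- switch(process,
    csr = {
      if (n_points < 0) frag_stop("n_points must be >= 0", "fragsim_error_parameter")
      list(process = "csr", n_points = n_points)
    },
    thomas = {
      params <- thomas_params(n_points, n_clusters, sigma, mode)
      list(process = "thomas", n_points = n_points, params = params)
    },
    strauss = {
      if (is.null(r)) r <- 1 / sqrt(n_points)
      params <- strauss_params(n_points, gamma, r, n_sweeps, burn_in)
      list(process = "strauss", n_points = n_points, params = params)
    })
  structure(spec, class = "species_spec")
}

#' @rdname species_spec
#' @param type landscape generator: `"fractal"` or `"disks"`.
#' @param habitat_amount habitat proportion p.
#' @param hurst Hurst factor (fractal landscapes).
#' @param levels raster recursion depth; side = `2^levels + 1`.
#' @param n_disks number of circular fragments (disk landscapes).
#' @export
landscape_spec <- function(type = c("fractal", "disks"), habitat_amount,
                           hurst = NULL, levels = 7L, n_disks = NULL) {
  type <- match.arg(type)
  if (is.na(habitat_amount) || habitat_amount < 0 || habitat_amount > 1) {
    frag_stop("habitat_amount must lie in [0, 1]", "fragsim_error_parameter")
  }
  if (type == "fractal") {
    if (is.null(hurst)) frag_stop("fractal landscapes need hurst",
                                  "fragsim_error_parameter")
    if (hurst <= 0 || hurst >= 1) {
      frag_stop("hurst must lie strictly in (0, 1)", "fragsim_error_parameter")
    }
    structure(list(type = "fractal", habitat_amount = habitat_amount,
                   hurst = hurst, levels = as.integer(levels)),
              class = "landscape_spec")
  } else {
    if (is.null(n_disks)) frag_stop("disk landscapes need n_disks",
                                    "fragsim_error_parameter")
    structure(list(type = "disks", habitat_amount = habitat_amount,
                   n_disks = as.integer(n_disks)),
              class = "landscape_spec")
  }
}

draw_pattern <- function(spec, window, seed) {
  switch(spec$process,
         csr = simulate_csr(spec$n_points, window, seed),
         thomas = simulate_thomas(spec$params, window, seed),
         strauss = simulate_strauss(spec$params, window, seed))
}

draw_landscape <- function(spec, window, seed) {
  if (spec$type == "fractal") {
    surf <- midpoint_displacement(spec$hurst, spec$levels, seed)
    threshold_to_habitat(surf, spec$habitat_amount, tie_seed = seed,
                         window = window)
  } else {
    make_disk_landscape(spec$n_disks, spec$habitat_amount, window, seed)
  }
}

#' Monte-Carlo estimate of abundance statistics and survival probability
#'
#' For each replicate a fresh point pattern and a fresh landscape are drawn
#' from deterministic child seeds, overlaid, and the surviving abundance
#' recorded. Both sources of randomness are redrawn every replicate because
#' the reported quantities average over species and landscape stochasticity
#' jointly (and CSR's independence of fragmentation only holds marginally
#' over landscapes at fixed habitat amount).
#'
#' @param species a [species_spec()].
#' @param landscape a [landscape_spec()].
#' @param n_reps number of replicate simulations (>= 2; the study design
#'   uses 1000).
#' @param master_seed master seed; per-replicate child seeds for the pattern
#'   and the landscape are derived from it deterministically.
#' @param window observation window.
#' @return object of class `survival_estimate`: `n_reps`, `mean_abundance`,
#'   `se_mean_abundance`, `cv_abundance` (`NA` when mean abundance is 0),
#'   `survival_prob`, `se_survival` (binomial), and the replicate
#'   `abundances` vector.
#' @examples
#' est <- estimate_survival(species_spec("csr", 10),
#'                          landscape_spec("fractal", 0.1, hurst = 0.5),
#'                          n_reps = 100, master_seed = 1)
#' est$survival_prob
#' @export
estimate_survival <- function(species, landscape, n_reps = 1000,
                              master_seed = 1L, window = unit_square()) {
  stopifnot(inherits(species, "species_spec"),
            inherits(landscape, "landscape_spec"))
  if (n_reps < 2) {
    frag_stop("n_reps must be >= 2 (cv is undefined otherwise)",
              "fragsim_error_parameter")
  }
  set.seed(master_seed)
  pattern_seeds <- sample.int(2147483646L, n_reps)
  landscape_seeds <- sample.int(2147483646L, n_reps)
  abundances <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    pat <- draw_pattern(species, window, pattern_seeds[i])
    map <- draw_landscape(landscape, window, landscape_seeds[i])
    abundances[i] <- overlay(pat, map)$abundance
  }
  m <- mean(abundances)
  s <- sd(abundances)
  q <- mean(abundances > 0)
  structure(list(n_reps = n_reps,
                 mean_abundance = m,
                 se_mean_abundance = s / sqrt(n_reps),
                 cv_abundance = if (m > 0) s / m else NA_real_,
                 survival_prob = q,
                 se_survival = sqrt(q * (1 - q) / n_reps),
                 abundances = abundances,
                 master_seed = master_seed),
            class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf(
    "survival estimate (%d reps): mean abundance %.3f (se %.3f), cv %.3f, survival %.4f (se %.4f)\n",
    x$n_reps, x$mean_abundance, x$se_mean_abundance, x$cv_abundance,
    x$survival_prob, x$se_survival))
  invisible(x)
}

#' Wilson score interval for a survival estimate
#'
#' Binomial interval that stays informative when the point estimate is 0 or
#' 1 (the plain binomial standard error degenerates there).
#'
#' @param q estimated proportion.
#' @param n number of replicates.
#' @param level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(q, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  centre <- (q + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(q * (1 - q) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Run one cell of the factorial design
#'
#' Wraps [estimate_survival()] for a single scenario (one combination of
#' species parameters, habitat amount and fragmentation) and returns a flat
#' one-row data frame carrying all parameters alongside the estimates, ready
#' for the long-format results table.
#'
#' @param cell a list or one-row data frame with fields `process`, `n_P`,
#'   `habitat_amount`, `n_reps`, `master_seed`, plus process-specific fields
#'   (`n_C`, `sigma` for thomas; `gamma` and optional `r` for strauss),
#'   landscape fields (`landscape_type`, `hurst` or `n_disks`) and optional
#'   `mode`, `levels`, `n_sweeps`.
#' @return one-row `data.frame` with columns `process`, `n_P`, `n_C`,
#'   `sigma`, `gamma`, `r`, `landscape_type`, `habitat_amount`, `hurst`,
#'   `n_reps`, `master_seed`, `mean_abundance`, `se_mean_abundance`,
#'   `cv_abundance`, `survival_prob`, `se_survival`.
#' @export
run_scenario_cell <- function(cell) {
  cell <- as.list(cell)
  grab <- function(name, default = NULL) {
    v <- cell[[name]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
  }
  process <- match.arg(cell$process, c("csr", "thomas", "strauss"))
  n_sweeps <- grab("n_sweeps", 1e5)
  species <- switch(process,
    csr = species_spec("csr", cell$n_P),
    thomas = species_spec("thomas", cell$n_P, n_clusters = cell$n_C,
                          sigma = cell$sigma, mode = grab("mode", "conditioned")),
    strauss = species_spec("strauss", cell$n_P, gamma = cell$gamma,
                           r = grab("r", 1 / sqrt(cell$n_P)),
                           n_sweeps = n_sweeps, burn_in = n_sweeps / 2))
  ltype <- grab("landscape_type", "fractal")
  landscape <- if (ltype == "fractal") {
    landscape_spec("fractal", cell$habitat_amount, hurst = cell$hurst,
                   levels = grab("levels", 7L))
  } else {
    landscape_spec("disks", cell$habitat_amount, n_disks = cell$n_disks)
  }
  if (cell$habitat_amount == 0) {
    # degenerate landscape: no habitat, extinction is certain
    est <- list(n_reps = cell$n_reps, mean_abundance = 0,
                se_mean_abundance = 0, cv_abundance = NA_real_,
                survival_prob = 0, se_survival = 0)
  } else {
    est <- estimate_survival(species, landscape, cell$n_reps,
                             cell$master_seed)
  }
  data.frame(process = process,
             n_P = cell$n_P,
             n_C = if (process == "thomas") cell$n_C else NA_real_,
             sigma = if (process == "thomas") cell$sigma else NA_real_,
             gamma = if (process == "strauss") cell$gamma else NA_real_,
             r = if (process == "strauss") grab("r", 1 / sqrt(cell$n_P)) else NA_real_,
             landscape_type = ltype,
             habitat_amount = cell$habitat_amount,
             hurst = if (ltype == "fractal") cell$hurst else NA_real_,
             n_reps = cell$n_reps,
             master_seed = cell$master_seed,
             mean_abundance = est$mean_abundance,
             se_mean_abundance = est$se_mean_abundance,
             cv_abundance = est$cv_abundance,
             survival_prob = est$survival_prob,
             se_survival = est$se_survival,
             stringsAsFactors = FALSE)
}
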