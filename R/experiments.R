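#' Factorial scenario configurations of the study design
#'
#' The three factorial designs crossed with the landscape grids:
#' * CSR: `n_P` in \{10, 100, 1000\};
#' * Thomas: `n_P` in \{10, 100, 1000\} x `n_C` in \{1, 2, 5, 10\} x
#'   `sigma` in \{0.01, 0.02, 0.05, 0.1\};
#' * Strauss: `n_P` in \{10, 100, 1000\} x `gamma` in \{0, 0.01, 0.1, 1\}.
#'
#' Landscapes vary habitat amount over \{0.01, 0.02, 0.05, 0.1, 0.2, 0.5\}
#' (a documented log-ish spacing of the designed 0.01-0.5 range) and the
#' Hurst factor over \{0.1, 0.3, 0.5, 0.7, 0.9\} (high to low fragmentation
#' per se). Every grid can be overridden before running.
#'
#' @param n_reps replicate simulations per scenario cell (design default
#'   1000).
#' @param master_seed master seed for the whole experiment.
#' @return named list of three `scenario_config` objects (`csr`, `thomas`,
#'   `strauss`), each holding a `species` data frame (one row per species
#'   cell), the landscape grids and replication settings.
#' @examples
#' g <- default_grids()
#' nrow(g$thomas$species)  # 48 species cells
#' @export
default_grids <- function(n_reps = 1000, master_seed = 1L) {
  habitat <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
  hurst <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cfg <- function(process, species) {
    structure(list(process = process, species = species,
                   habitat_amount = habitat, hurst = hurst,
                   landscape_type = "fractal", levels = 7L,
                   n_reps = n_reps, master_seed = master_seed),
              class = "scenario_config")
  }
  list(
    csr = cfg("csr", expand.grid(n_P = c(10, 100, 1000))),
    thomas = cfg("thomas", expand.grid(n_P = c(10, 100, 1000),
                                       n_C = c(1, 2, 5, 10),
                                       sigma = c(0.01, 0.02, 0.05, 0.1))),
    strauss = cfg("strauss", expand.grid(n_P = c(10, 100, 1000),
                                         gamma = c(0, 0.01, 0.1, 1)))
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario config: %s, %d species cells x %d habitat x %d hurst, %d reps\n",
              x$process, nrow(x$species), length(x$habitat_amount),
              length(x$hurst), x$n_reps))
  invisible(x)
}

#' Expand a scenario configuration into its cell table
#'
#' One row per cell of the factorial design (species cell x habitat amount x
#' fragmentation level), with a deterministic per-cell child seed derived
#' from the master seed.
#'
#' @param config a `scenario_config` from [default_grids()] (fields can be
#'   overridden first).
#' @return data frame of scenario cells consumable by [run_scenario_cell()].
#' @export
scenario_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  species <- config$species
  species$species_cell <- seq_len(nrow(species))
  land <- if (config$landscape_type == "fractal") {
    expand.grid(habitat_amount = config$habitat_amount, hurst = config$hurst)
  } else {
    expand.grid(habitat_amount = config$habitat_amount,
                n_disks = config$n_disks)
  }
  cells <- merge(species, land, by = NULL)  # cartesian product
  cells$process <- config$process
  cells$landscape_type <- config$landscape_type
  cells$levels <- config$levels
  cells$n_reps <- config$n_reps
  set.seed(config$master_seed)
  cells$master_seed <- sample.int(2147483646L, nrow(cells))
  cells
}

#' Run a scenario experiment
#'
#' Iterates over all cells of a configuration, estimating abundance
#' statistics and survival probability for each, and (optionally) writes the
#' long-format results CSV incrementally so partial output survives
#' interruption. A failed cell is logged and marked (`status = "failed"`),
#' never fatal. Re-running with the same configuration reproduces the CSV
#' byte for byte.
#'
#' @param config a `scenario_config` (see [default_grids()]).
#' @param output_csv optional path for the incremental results CSV.
#' @param log_file optional path for a plain-text progress log (per-cell
#'   parameters, child seed and timing).
#' @param quiet suppress console progress messages.
#' @return data frame with one row per scenario cell: all parameters plus
#'   `mean_abundance`, `se_mean_abundance`, `cv_abundance`, `survival_prob`,
#'   `se_survival` and `status`.
#' @export
run_experiment <- function(config, output_csv = NULL, log_file = NULL,
                           quiet = FALSE) {
  cells <- scenario_table(config)
  out <- vector("list", nrow(cells))
  logline <- function(msg) {
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
    if (!quiet) message(msg)
  }
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    t0 <- Sys.time()
    row <- tryCatch({
      r <- run_scenario_cell(cell)
      r$status <- "ok"
      r
    }, error = function(e) {
      data.frame(process = cell$process, n_P = cell$n_P,
                 n_C = if (!is.null(cell$n_C)) cell$n_C else NA_real_,
                 sigma = if (!is.null(cell$sigma)) cell$sigma else NA_real_,
                 gamma = if (!is.null(cell$gamma)) cell$gamma else NA_real_,
                 r = NA_real_, landscape_type = cell$landscape_type,
                 habitat_amount = cell$habitat_amount,
                 hurst = if (!is.null(cell$hurst)) cell$hurst else NA_real_,
                 n_reps = cell$n_reps, master_seed = cell$master_seed,
                 mean_abundance = NA_real_, se_mean_abundance = NA_real_,
                 cv_abundance = NA_real_, survival_prob = NA_real_,
                 se_survival = NA_real_, status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- row
    if (!is.null(output_csv)) {
      write.table(row, output_csv, sep = ",", row.names = FALSE,
                  col.names = i == 1, append = i > 1, qmethod = "double")
    }
    logline(sprintf(
      "cell %d/%d %s n_P=%g p=%g %s seed=%d [%.2fs] %s",
      i, nrow(cells), cell$process, cell$n_P, cell$habitat_amount,
      if (!is.null(cell$hurst)) sprintf("H=%g", cell$hurst) else "",
      cell$master_seed, as.numeric(Sys.time() - t0, units = "secs"),
      row$status))
  }
  do.call(rbind, out)
}

#' Panel plot of survival (or abundance) against fragmentation per se
#'
#' Reproduces the layout of the study figures: the x axis runs from low
#' fragmentation per se (Hurst factor 0.9) on the left to high fragmentation
#' (0.1) on the right, one line per habitat amount, optionally faceted by
#' scenario parameters (e.g. rows `sigma` x columns `n_C` for the aggregated
#' design, rows `n_P` x columns `gamma` for the regular design).
#'
#' @param results results table from [run_experiment()] or
#'   [run_scenario_cell()] rows.
#' @param response column to draw: `"survival_prob"`, `"mean_abundance"` or
#'   `"cv_abundance"`.
#' @param rows,cols optional faceting variable names.
#' @param file optional output path (png or pdf, via [ggplot2::ggsave()]).
#' @return the ggplot object (invisibly `NULL` with a warning for an empty
#'   table).
#' @export
plot_survival_curves <- function(results, response = "survival_prob",
                                 rows = NULL, cols = NULL, file = NULL) {
  needed <- c("hurst", "habitat_amount", response)
  if (!all(needed %in% names(results))) {
    frag_stop(paste("results table lacks columns:",
                    paste(setdiff(needed, names(results)), collapse = ", ")),
              "fragsim_error_schema")
  }
  if (!nrow(results)) {
    warning("empty results table; nothing to plot")
    return(invisible(NULL))
  }
  d <- results
  d$fragmentation <- factor(d$hurst, levels = sort(unique(d$hurst),
                                                   decreasing = TRUE))
  d$habitat <- factor(d$habitat_amount)
  d$value <- d[[response]]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = fragmentation, y = value,
                                       colour = habitat, group = habitat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "fragmentation per se (Hurst factor, low to high)",
                  y = response, colour = "habitat amount") +
    ggplot2::theme_minimal()
  if (!is.null(rows) || !is.null(cols)) {
    row_f <- if (is.null(rows)) "." else rows
    col_f <- if (is.null(cols)) "." else cols
    p <- p + ggplot2::facet_grid(stats::as.formula(paste(row_f, "~", col_f)),
                                 labeller = ggplot2::label_both)
  }
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 6)
  p
}

#' Compare analytic and simulated survival on disk landscapes
#'
#' For each (sigma, habitat amount) combination, runs the Poisson-mode
#' Thomas simulation on Boolean disk landscapes and the analytic
#' void-probability solution on the same fragment-placement distribution,
#' returning both estimates with their standard errors and the
#' difference-to-pooled-SE ratio.
#'
#' @param rho,mu Thomas intensity and mean cluster size (`n_P = rho * mu`
#'   on the unit square).
#' @param sigmas vector of cluster spreads to compare.
#' @param habitat_amounts vector of nominal habitat amounts.
#' @param n_disks fragments per landscape.
#' @param n_reps simulation replicates per combination.
#' @param n_landscapes Monte-Carlo fragment configurations for the analytic
#'   average.
#' @param grid_n torus grid resolution of the analytic inner integral.
#' @param master_seed master seed.
#' @return data frame with one row per (sigma, habitat amount) combination.
#' @export
compare_analytic <- function(rho = 5, mu = 20, sigmas = c(0.01, 0.02, 0.05),
                             habitat_amounts = c(0.05, 0.1, 0.2),
                             n_disks = 10, n_reps = 1000, n_landscapes = 100,
                             grid_n = 512L, master_seed = 1L) {
  grid <- expand.grid(sigma = sigmas, habitat_amount = habitat_amounts)
  set.seed(master_seed)
  seeds <- matrix(sample.int(2147483646L, 2 * nrow(grid)), ncol = 2)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sg <- grid$sigma[i]; p <- grid$habitat_amount[i]
    species <- species_spec("thomas", n_points = rho * mu,
                            n_clusters = rho, sigma = sg, mode = "poisson")
    sim <- estimate_survival(species,
                             landscape_spec("disks", p, n_disks = n_disks),
                             n_reps = n_reps, master_seed = seeds[i, 1])
    ana <- survival_thomas_disks(
      analytic_thomas_spec(rho, mu, sg, n_disks, p),
      n_landscapes = n_landscapes, grid_n = grid_n, seed = seeds[i, 2])
    pooled <- sqrt(sim$se_survival^2 + ana$se^2)
    out[[i]] <- data.frame(sigma = sg, habitat_amount = p,
                           survival_sim = sim$survival_prob,
                           se_sim = sim$se_survival,
                           survival_analytic = ana$survival,
                           se_analytic = ana$se,
                           diff = ana$survival - sim$survival_prob,
                           pooled_se = pooled,
                           z = (ana$survival - sim$survival_prob) /
                             max(pooled, .Machine$double.eps),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
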