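test_that("CSR survival closed form and its monotonicity", {
  expect_equal(survival_csr(1, 0.3), 0.3)
  expect_equal(survival_csr(0, 0.3), 0)
  expect_equal(survival_csr(10, 0.05), 1 - 0.95^10, tolerance = 1e-12)

  n <- c(1, 5, 10, 50, 100)
  p <- c(0.01, 0.05, 0.1, 0.3)
  for (pp in p) expect_true(all(diff(survival_csr(n, pp)) > 0))
  for (nn in n) expect_true(all(diff(survival_csr(nn, p)) > 0))
  # union bound (tolerance for floating-point ties at n = 1)
  grid <- expand.grid(n = n, p = p)
  expect_true(all(survival_csr(grid$n, grid$p) <=
                    pmin(1, grid$n * grid$p) + 1e-12))
})

test_that("gaussian_disk_mass agrees with brute-force 2-D quadrature", {
  # Rayleigh radial CDF at d = 0 and the R -> Inf limit
  expect_equal(gaussian_disk_mass(0, 0.05, 0.1),
               1 - exp(-0.1^2 / (2 * 0.05^2)), tolerance = 1e-12)
  expect_equal(gaussian_disk_mass(0.3, 0.05, 10), 1, tolerance = 1e-9)

  # brute-force numerical oracle: polar integration of the Rayleigh radial
  # density against the exact chord angle subtended by the disk — a route
  # fully independent of the noncentral-chi-square CDF
  quad_oracle <- function(d, sigma, R) {
    if (d == 0) return(1 - exp(-R^2 / (2 * sigma^2)))
    f <- function(t) {
      cosang <- pmin(1, pmax(-1, (t^2 + d^2 - R^2) / (2 * t * d)))
      t / sigma^2 * exp(-t^2 / (2 * sigma^2)) * acos(cosang) / pi
    }
    stats::integrate(f, max(1e-12, d - R), d + R, rel.tol = 1e-11,
                     abs.tol = 1e-13, subdivisions = 2000L)$value
  }
  cases <- expand.grid(d = c(0, 0.05, 0.1, 0.3),
                       sigma = c(0.02, 0.05, 0.1),
                       R = c(0.05, 0.1, 0.2))
  for (i in seq_len(nrow(cases))) {
    got <- gaussian_disk_mass(cases$d[i], cases$sigma[i], cases$R[i])
    expect_lt(abs(got - quad_oracle(cases$d[i], cases$sigma[i], cases$R[i])),
              1e-6)
  }

  expect_error(gaussian_disk_mass(-1, 0.1, 0.1),
               class = "fragsim_error_parameter")
})

test_that("void-probability survival agrees with an independent one-disk oracle", {
  # single disk on the torus: conditional survival is translation-invariant,
  # so the FFT-convolution route must match a direct quadrature built on the
  # exact noncentral-chi-square disk mass
  for (sg in c(0.02, 0.1)) {
    spec <- analytic_thomas_spec(rho = 5, mu = 20, sigma = sg, n_disks = 1,
                                 habitat_amount = 0.15)
    got <- survival_thomas_disks(spec, n_landscapes = 3, seed = 1)
    want <- one_disk_survival_oracle(5, 20, sg, spec$radius)
    expect_equal(got$survival, want, tolerance = 0.01)
    # translation invariance up to sub-cell rasterization jitter of the disk
    expect_lt(stats::sd(got$per_landscape), 1e-3)
  }
})

test_that("degenerate cluster limit: survival approaches centre-in-disk probability", {
  # sigma -> 0 collapses each cluster onto its centre, so conditional on one
  # disk the survival is 1 - exp(-rho * piR^2 * (1 - exp(-mu)))
  spec <- analytic_thomas_spec(rho = 1, mu = 2, sigma = 0.003, n_disks = 1,
                               habitat_amount = 0.25)
  got <- survival_thomas_disks(spec, n_landscapes = 3, seed = 2)
  want <- 1 - exp(-pi * spec$radius^2 * (1 - exp(-2)))
  expect_equal(got$survival, want, tolerance = 0.02)
})

test_that("wide kernels reduce the cluster process toward the CSR closed form", {
  # sigma of 5 window sides spreads offspring uniformly over the torus; with
  # a single disk (realized = nominal coverage) the survival must sit within
  # 0.01 of the CSR form for the same expected abundance
  spec <- analytic_thomas_spec(rho = 5, mu = 20, sigma = 5, n_disks = 1,
                               habitat_amount = 0.2)
  got <- survival_thomas_disks(spec, n_landscapes = 3, seed = 3)
  expect_lt(abs(got$survival - survival_csr(100, 0.2)), 0.01)
})

test_that("analytic and simulated survival agree on a matched disk scenario", {
  cmp <- compare_analytic(sigmas = 0.02, habitat_amounts = 0.1,
                          n_disks = 10, n_reps = 400, n_landscapes = 50,
                          master_seed = 5)
  expect_lt(abs(cmp$z), 4)
})
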