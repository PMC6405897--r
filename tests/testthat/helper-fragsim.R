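# shared test utilities

pooled_se <- function(a, b) sqrt(a^2 + b^2)

# Exact distribution of the Strauss pair statistic s for n = 3 points on a
# discretized unit torus: brute-force combinatorial enumeration over the
# g^2-site state space. The close-pair graph on the torus grid is
# vertex-transitive, so triples with 0..3 close pairs can be counted from the
# common degree, the cherry count and the triangle count; weighting by
# gamma^s gives the exact discrete Strauss distribution. Independent of the
# Metropolis-Hastings code path it validates.
exact_strauss3_distribution <- function(gamma, r, g = 128L) {
  d <- (0:(g - 1)) / g
  d <- pmin(d, 1 - d)
  C <- outer(d^2, d^2, "+") < r^2
  C[1, 1] <- FALSE
  nsite <- as.numeric(g)^2
  deg <- sum(C)                         # same for every site
  m <- nsite * deg / 2                  # close pairs
  cherries <- nsite * choose(deg, 2)    # paths of length 2
  off <- which(C, arr.ind = TRUE) - 1L
  t_ord <- 0
  for (k in seq_len(nrow(off))) {
    ri <- ((0:(g - 1)) - off[k, 1]) %% g + 1L
    ci <- ((0:(g - 1)) - off[k, 2]) %% g + 1L
    t_ord <- t_ord + sum(C & C[ri, ci])
  }
  triangles <- nsite * t_ord / 6
  E3 <- triangles
  E2 <- cherries - 3 * triangles
  E1 <- m * (nsite - 2) - 2 * E2 - 3 * E3
  E0 <- choose(nsite, 3) - E1 - E2 - E3
  w <- c(E0, E1, E2, E3) * gamma^(0:3)
  w / sum(w)
}

# independent survival oracle for a single-disk landscape: on the torus the
# conditional survival is translation-invariant, so one fixed centre and a
# plain quadrature over cluster-centre positions using the exact
# Marcum-Q/noncentral-chi-square disk mass suffices
one_disk_survival_oracle <- function(rho, mu, sigma, radius, m = 256L) {
  gc <- (seq_len(m) - 0.5) / m
  dx <- abs(gc - 0.5); dx <- pmin(dx, 1 - dx)
  dd <- sqrt(outer(dx^2, dx^2, "+"))
  q <- gaussian_disk_mass(as.vector(dd), sigma, radius)
  1 - exp(-rho * mean(1 - exp(-mu * q)))
}
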