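---
title: "Quantifying geometric fragmentation effects with fragsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying geometric fragmentation effects with fragsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsim)
```

## The model

When natural habitat is converted to a hostile matrix, two very different
things happen to a species. Individuals that stand in the matrix are lost
purely because of where they stood — a *geometric* effect that depends only
on the spatial arrangement of individuals relative to the remaining habitat
fragments. Everything else (demographic stochasticity in small fragments,
edge effects, isolation, altered interactions) is a *demographic* effect.
fragsim quantifies the geometric component alone, as a null model: habitat
fragments act as a cookie-cutter, every individual in habitat survives,
every individual in the matrix dies, and landscape-scale survival means at
least one individual remains in habitat.

The framework has three ingredients:

1. **Species distributions** in the continuous unit square, as point
   processes: complete spatial randomness (`simulate_csr()`), the Thomas
   cluster process for aggregation (`simulate_thomas()`), and the Strauss
   inhibition process for regularity (`simulate_strauss()`).
2. **Fragmented landscapes** with independently controlled habitat amount
   and fragmentation per se: fractal surfaces from midpoint displacement
   (`midpoint_displacement()`) thresholded by rank
   (`threshold_to_habitat()`), or Boolean landscapes of equal-radius disks
   (`make_disk_landscape()`).
3. **Cookie-cutter sampling**: `overlay()` intersects a pattern with a map;
   `estimate_survival()` Monte-Carloes abundance statistics and survival
   probability over replicate draws of both.

An analytic cross-check (`survival_thomas_disks()`) computes the same
survival probability for the Thomas process on disk landscapes from the
void probability of the cluster-process generating functional, with no
simulation of individuals at all.

## Species distributions and their parameters

Every point is one individual. All three processes run on the **toroidal**
unit square by default: internally generated patterns wrap, which keeps
intensity spatially uniform and avoids edge artefacts in nearest-neighbour
statistics. Diagnostics on external (field) data should use
`unit_square("planar")` instead.

**CSR** places `n` points independently and uniformly; it is the reference
against which aggregation and regularity are measured. Under CSR, survival
has the closed form `survival_csr(n, p)` = \(1 - (1-p)^n\), independent of
how the habitat is configured.

**Thomas process.** Cluster centres follow CSR with intensity \(\rho\);
each centre receives a Poisson(\(\mu\)) number of offspring displaced by an
isotropic bivariate Gaussian with per-axis standard deviation \(\sigma\).
Expected abundance is \(n_P = \rho A \mu\) with \(n_C = \rho A\) clusters.
Two modes are provided because the study design and the analytic theory
make different assumptions:

* `conditioned` (default): exactly `n_clusters` centres and exactly
  `n_points` offspring, allocated by an equal-probability multinomial, so
  every replicate has the same abundance — matching factorial designs that
  fix abundance at, say, 100 individuals.
* `poisson`: Poisson centre count and Poisson offspring counts — the
  textbook process assumed by the void-probability solution.

A note on the kernel: the isotropic Gaussian displacement density is
implemented with per-axis variance \(\sigma^2\), i.e. the exponent
\(-(x^2+y^2)/(2\sigma^2)\), the standard normalized form used throughout
the cluster-process literature. One occasionally sees the same kernel
printed with \(-(x^2+y^2)/\sigma^2\) in the exponent, which does not
integrate to one; we flag this rather than silently following it.

Offspring falling outside the window are wrapped toroidally rather than
rejected: rejection would thin peripheral clusters and make the intensity
spatially non-uniform.

**Strauss process.** The regular pattern is a Gibbs process with density
\(\propto \gamma^{s(x)}\), where \(s(x)\) counts point pairs closer than
the interaction radius \(r\). \(\gamma = 1\) is exactly CSR; \(\gamma = 0\)
is a hard core with no pair closer than \(r\). The default
\(r = 1/\sqrt{N}\) is the spacing of a perfect lattice of \(N\) points
covering the landscape. Sampling is fixed-\(n\) single-point
Metropolis-Hastings (in C++): each update proposes, with probability 1/2, a
fresh uniform location (global move, mixes across inhibition gaps),
otherwise a Gaussian jitter of scale \(r/2\) (local move); the acceptance
ratio is \(\gamma^{\Delta s}\) with the \(\gamma = 0\) convention
\(0^0 = 1\). Defaults are \(10^5\) updates with the first half treated as
burn-in; both are configurable via `strauss_params()`.

Two numerical choices deserve mention:

* *Hard-core initialization.* At the default radius the packing fraction is
  \(\pi/4 \approx 0.785\), beyond what random dart throwing can reach
  (random sequential adsorption jams near 0.547). When \(N\) is a sum of
  two squares \(a^2 + b^2\) — which covers the design abundances 10, 100
  and 1000 — the scaled-rotated integer lattice
  \(\{(ax - by,\; bx + ay)/N\}\) wraps exactly onto the unit torus with
  \(N\) points at minimum spacing exactly \(1/\sqrt{N}\), giving a
  deterministic feasible start. Otherwise dart throwing with bounded
  attempts is tried and an explicit feasibility error raised on failure.
* *Tie convention.* Pair distances within a relative \(10^{-12}\) of \(r\)
  count as equal to \(r\) (not closer), in both `pair_count()` and the
  sampler, so lattice starts at spacing exactly \(r\) have \(s = 0\) under
  floating-point arithmetic. Ties are measure-zero for continuous patterns.

The sampler is validated two independent ways: \(\gamma = 1\) must be
statistically indistinguishable from CSR, and for \(n = 3\) the sampled
distribution of \(s\) is compared against the exact distribution computed
by brute-force combinatorial enumeration over a discretized torus
(the close-pair graph on the grid is vertex-transitive, so triples with
0-3 close pairs can be counted exactly from degree, cherry and triangle
counts). Agreement is required within 2% total variation.

## Fragmented landscapes

`midpoint_displacement(hurst, levels)` runs classic diamond-square without
random additions: corners from standard normals, and at recursion level
\(l\) both midpoint steps perturb with standard deviation \((1/2)^{lH}\).
Edge midpoints average their three in-grid neighbours. The Hurst factor
\(H \in (0,1)\) sets the roughness (fractal dimension \(D = 3 - H\)): low
\(H\) gives rugged surfaces whose thresholded habitat is scattered into
many small fragments (high fragmentation per se), high \(H\) gives smooth
surfaces with few contiguous fragments. The default `levels = 7` yields the
129 × 129 rasters of the study design.

`threshold_to_habitat()` converts a surface to a binary map by **rank**,
not by a fixed elevation: exactly
\(k = \lfloor p \cdot n_\mathrm{cells} + 0.5 \rfloor\) (round half up) of
the highest cells become habitat. This makes the habitat amount exact for
every single map — important because the whole point of the design is to
vary fragmentation per se at *fixed* habitat amount. Ties at the cut value
are broken uniformly at random with a recorded seed; for continuous
surfaces ties are measure-zero, so this only matters for degenerate inputs.

Raster cells tile the unit square exactly (cell size \(1/\mathrm{side}\)),
cells are half-open with the \(x = 1\) and \(y = 1\) boundaries assigned to
the last cell, so every point of the window belongs to exactly one cell.

`make_disk_landscape()` places `n_disks` centres uniformly on the torus and
solves the common radius from \(n \pi R^2 = pA\). Overlaps are permitted —
the Boolean-model assumption under which the analytic solution is
tractable — so the nominal habitat amount `p` is recorded and
`realized_coverage()` reports the (possibly smaller) realized fraction.

`count_patches()` is the one landscape metric shipped: connected components
of the habitat cells under rook adjacency (via igraph), used to verify that
lowering \(H\) from 0.9 to 0.1 multiplies the number of fragments.

## Monte-Carlo estimation

`estimate_survival()` redraws **both** the point pattern and the landscape
in every replicate, from deterministic child seeds derived from one master
seed. The reported quantities — mean abundance, its standard error, the
coefficient of variation of abundance, survival probability with a binomial
standard error — average over both sources of randomness; CSR's
independence of fragmentation per se holds marginally over landscapes at
fixed habitat amount, which is the sense in which the design intends it.
The study default is 1000 replicates per scenario cell.

Conventions: the cv is reported as missing (not zero) when mean abundance
is zero; survival estimates of exactly 0 or 1 are reported as-is, with
`wilson_interval()` available where a degenerate binomial SE would mislead;
`n_reps = 1` is rejected because the cv is undefined.

`default_grids()` returns the three factorial designs (3 CSR cells, 48
Thomas cells, 12 Strauss cells) crossed with habitat amounts
{0.01, 0.02, 0.05, 0.1, 0.2, 0.5} and Hurst factors
{0.1, 0.3, 0.5, 0.7, 0.9}. The design prescribes the 0.01-0.5 habitat
range and the 0.1-0.9 Hurst range; the specific grid values are this
package's documented choice (log-ish spacing for habitat, even spacing for
\(H\)) and can be overridden in the config. `run_experiment()` writes the
long-format CSV incrementally, logs per-cell seeds and timing, marks failed
cells rather than aborting, and byte-reproduces its output under a fixed
master seed. `plot_survival_curves()` draws the survival-vs-fragmentation
panels with the x axis running from \(H = 0.9\) (low fragmentation) to
\(H = 0.1\) (high), one line per habitat amount.

## The analytic cross-check

For the Poisson-mode Thomas process on a disk landscape \(W\), the void
probability follows from the generating functional of the Poisson cluster
process, giving the conditional survival

\[
S(W) \;=\; 1 - \exp\!\Big(-\rho \int \big[1 - e^{-\mu\, q(c, W)}\big]\,dc\Big),
\]

where \(q(c, W)\) is the probability that one offspring of a cluster
centred at \(c\) lands in \(W\). For a single disk at distance \(d\),
\(q\) is exact: the squared distance of the Gaussian offset to the disk
centre is \(\sigma^2\) times a noncentral \(\chi^2_2\), so
`gaussian_disk_mass()` is `pchisq((R/sigma)^2, 2, (d/sigma)^2)`
(equivalently the Marcum Q-function). For a union of possibly overlapping
disks, \(q(\cdot, W)\) is computed in one stroke as the circular
convolution of the disk-coverage indicator with the wrapped Gaussian
kernel, evaluated by 2-D FFT on the torus — periodic boundaries are exact
there, overlaps need no inclusion-exclusion, and the same grid then
evaluates the outer integral over \(c\). The average over random fragment
placements is Monte-Carlo over centre draws with a reported standard error.

Numerical choices: default grid 512 × 512 (refining to 1024 moves results
by \(\sim 2\times10^{-4}\)); the coverage indicator is supersampled 2× to
soften rasterization of disk edges; the wrapped kernel sums Gaussian images
out to \(6\sigma\), so spreads up to several window sides are handled, and
the \(\sigma \to \infty\) limit correctly collapses to the covered-fraction
(CSR-like) case. The FFT route is validated against a fully independent
quadrature built on the noncentral-\(\chi^2\) mass for single-disk
landscapes (where translation invariance on the torus makes the conditional
survival a constant), against the \(\sigma \to 0\) collapse
\(1 - \exp(-\rho \pi R^2 (1 - e^{-\mu}))\), and against Poisson-mode
simulation on matched disk ensembles.

Because neither the analytic route nor the simulation feeds the other, the
agreement required by the test suite (within 3 Monte-Carlo standard errors
across a \(\sigma \times p\) grid) is a genuine two-sided check of both
implementations.

## What the generator does and does not emulate

The synthetic scenarios capture exactly the ingredients the geometric
argument needs: fixed or Poisson abundances, tunable aggregation and
regularity, habitat amount controlled exactly per map, and fragmentation
per se varied independently of it. They deliberately do not emulate
features of real data to which the geometric null is meant to be compared:
habitat loss is spatially independent of the species distribution (no
preferential conversion of, say, valleys), conversion is instantaneous (no
time lags, no matrix survival), there is one species per pattern, and the
landscapes are statistically stationary. A passing test suite therefore
demonstrates the internal correctness of the geometric machinery, not that
any real landscape behaves like a fractal raster.

## Design decisions taken where the design was open

* Whether total abundance was fixed or Poisson in the original factorial
  runs is not recoverable; figure captions fix abundance exactly, so the
  conditioned mode is the default and the Poisson mode exists for the
  analytic comparison.
* A fresh landscape is generated for every replicate (reuse would
  correlate replicates and change the meaning of the standard errors).
* Disk fragments are placed uniformly with overlaps permitted — the
  placement model under which the generating-functional route is exact;
  fixed count rather than Poisson count of fragments, with the radius
  solved from the nominal coverage.
* Standard errors on survival and mean abundance are reported throughout;
  these are engineering additions for testability, not claims about the
  original figures.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the scenarios at the sizes the
properties need rather than the full 63-species-cell × 30-landscape-cell
factorial: 10 000 replicates where closed-form agreement at three binomial
standard errors is asserted, 1000-2000 replicates for orderings and
sign checks, 100 fragment configurations for the analytic average, and 100
replicate map pairs for the patch-count ordering. The full factorial is a
single `run_experiment()` call away and scales linearly in replicates and
cells.

## Known limitations

* The Strauss sampler is a finite MCMC run; at \(\gamma\) very close to 0
  and densities near the packing bound, mixing slows and the returned
  pattern retains memory of the lattice initialization. The hard-core
  guarantee (\(s = 0\)) holds regardless.
* The analytic inner integral is grid-based; for \(\sigma\) far below
  \(2 \times 10^{-3}\) (the default cell size) the kernel is
  under-resolved — use a larger `grid_n`, or the \(\sigma \to 0\) closed
  form.
* `nn_distances()` and `pair_count()` build full distance matrices
  (\(O(n^2)\) memory), fine for the design's abundances, not for millions
  of points.
* Landscape rasters are square with side \(2^\mathrm{levels} + 1\);
  arbitrary rectangular rasters are supported only through `read_asc()`.
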