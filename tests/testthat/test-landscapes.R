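test_that("midpoint displacement builds reproducible fractal surfaces", {
  s <- midpoint_displacement(0.5, levels = 7, seed = 1)
  expect_equal(dim(s$values), c(129, 129))
  expect_true(all(is.finite(s$values)))
  expect_equal(dim(midpoint_displacement(0.5, levels = 5, seed = 1)$values),
               c(33, 33))

  expect_identical(midpoint_displacement(0.7, 7, seed = 9)$values,
                   midpoint_displacement(0.7, 7, seed = 9)$values)

  # smoothness grows with the Hurst factor: mean absolute difference of
  # horizontally adjacent cells is smaller for H = 0.9 than for H = 0.1
  adj <- function(H, seed) {
    v <- midpoint_displacement(H, 7, seed = seed)$values
    mean(abs(v[-1, ] - v[-nrow(v), ]))
  }
  rough <- vapply(1:100, function(s) adj(0.1, s), numeric(1))
  smooth <- vapply(1:100, function(s) adj(0.9, 100 + s), numeric(1))
  expect_lt(mean(smooth), mean(rough))
  expect_true(all(smooth < rough))

  expect_error(midpoint_displacement(0), class = "fragsim_error_parameter")
  expect_error(midpoint_displacement(1), class = "fragsim_error_parameter")
  expect_error(midpoint_displacement(0.5, levels = 0),
               class = "fragsim_error_parameter")
})

test_that("thresholding yields exact habitat amounts with random tie-breaks", {
  s <- midpoint_displacement(0.5, 7, seed = 2)
  expect_equal(sum(threshold_to_habitat(s, 0)$grid), 0)
  expect_equal(sum(threshold_to_habitat(s, 1)$grid), 16641)
  expect_equal(sum(threshold_to_habitat(s, 0.2, tie_seed = 1)$grid), 3328)
  expect_equal(sum(threshold_to_habitat(s, 0.5, tie_seed = 1)$grid), 8321)

  # exactness holds across H and p (round-half-up of p * 16641)
  for (H in c(0.1, 0.9)) {
    surf <- midpoint_displacement(H, 7, seed = 31)
    for (p in c(0.01, 0.05, 0.33)) {
      expect_equal(sum(threshold_to_habitat(surf, p, tie_seed = 5)$grid),
                   floor(p * 16641 + 0.5))
    }
  }

  # ties at the cut value are resolved to the exact count
  tied <- structure(list(values = matrix(1, 9, 9), hurst = 0.5, levels = 3L,
                         seed = 1L), class = "fractal_surface")
  expect_equal(sum(threshold_to_habitat(tied, 0.5, tie_seed = 3)$grid),
               floor(0.5 * 81 + 0.5))
})

test_that("fragmentation per se ordering: rough surfaces give more patches", {
  patches <- function(H, seed) {
    count_patches(threshold_to_habitat(midpoint_displacement(H, 7, seed),
                                       0.2, tie_seed = seed))
  }
  n_rough <- vapply(1:20, function(s) patches(0.1, s), numeric(1))
  n_smooth <- vapply(1:20, function(s) patches(0.9, s), numeric(1))
  expect_true(all(n_rough > n_smooth))
})

test_that("CSR points land in habitat with probability p for any H", {
  for (H in c(0.1, 0.5, 0.9)) {
    hits <- 0
    for (i in 1:60) {
      m <- threshold_to_habitat(midpoint_displacement(H, 7, seed = 5000 + i),
                                0.2, tie_seed = i)
      pts <- simulate_csr(250, seed = 6000 + i)
      hits <- hits + sum(is_habitat(m, pts$x, pts$y))
    }
    phat <- hits / (60 * 250)
    expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / (60 * 250)))
  }
})

test_that("raster point-in-habitat uses half-open cells with closed top edge", {
  m <- threshold_to_habitat(midpoint_displacement(0.5, 7, seed = 3), 1)
  expect_true(all(is_habitat(m, c(0, 0.5, 1), c(0, 0.5, 1))))

  # the (1, 1) corner maps to the last cell without error
  g <- matrix(FALSE, 129, 129); g[129, 129] <- TRUE
  corner <- habitat_map(g)
  expect_true(is_habitat(corner, 1, 1))
  expect_false(is_habitat(corner, 0.5, 0.5))

  # 2x2 cell convention: grid[1, 1] is the lower-left quadrant
  ll <- habitat_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_true(is_habitat(ll, 0.1, 0.1))
  expect_false(is_habitat(ll, 0.9, 0.1))
  expect_false(is_habitat(ll, 0.1, 0.9))

  expect_error(is_habitat(ll, 1.2, 0.5), class = "fragsim_error_window")
})

test_that("disk landscapes solve the radius from the nominal habitat amount", {
  dl1 <- make_disk_landscape(1, 0.25, seed = 1)
  expect_equal(dl1$radius, sqrt(0.25 / pi), tolerance = 1e-12)
  expect_equal(make_disk_landscape(4, 0.25, seed = 1)$radius,
               sqrt(0.25 / (4 * pi)), tolerance = 1e-12)

  # a single disk cannot overlap itself: realized coverage = nominal p
  expect_equal(realized_coverage(dl1, grid_n = 1024), 0.25, tolerance = 2e-3)

  # overlapping disks cover less than nominal
  dl <- make_disk_landscape(30, 0.4, seed = 2)
  expect_lt(realized_coverage(dl), 0.4)

  # radial containment test, toroidal metric
  one <- structure(list(cx = 0.5, cy = 0.5, radius = 0.1,
                        habitat_amount = pi * 0.01, window = unit_square(),
                        seed = 1L), class = "disk_landscape")
  expect_true(is_habitat(one, 0.5, 0.59))
  expect_false(is_habitat(one, 0.5, 0.61))
  wrap <- structure(list(cx = 0.02, cy = 0.5, radius = 0.1,
                         habitat_amount = pi * 0.01, window = unit_square(),
                         seed = 1L), class = "disk_landscape")
  expect_true(is_habitat(wrap, 0.97, 0.5))

  expect_error(make_disk_landscape(1, 0.9, seed = 1),
               class = "fragsim_error_parameter")
})
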