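one_carbon <- data.frame(elem = "C", x = 0, y = 0, z = 0)

test_that("grid construction covers the structure plus margin", {
  g <- build_grid(one_carbon, spacing = 1, margin = 2)
  expect_equal(g$dim, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-2, -2, -2))
  pts <- grid_points(g)
  expect_equal(nrow(pts), 125L)
  # center point sits on the atom
  expect_true(any(rowSums(abs(pts)) < 1e-12))

  two <- data.frame(elem = c("C", "C"), x = c(0, 10), y = 0, z = 0)
  g2 <- build_grid(two, spacing = 1, margin = 0)
  expect_equal(g2$dim, c(11L, 1L, 1L))

  expect_error(build_grid(one_carbon, spacing = 0), "spacing")
  expect_error(build_grid(one_carbon, spacing = -1), "spacing")
})

test_that("the far-field probe energy is exactly the entropy constant", {
  p <- default_probe_params()
  expect_equal(dry_point_energy(c(50, 50, 50), one_carbon, p), -0.848)
  # every grid point beyond the cutoff radius evaluates to delta_s exactly
  g <- build_grid(one_carbon, spacing = 2, margin = 12)
  f <- compute_field(one_carbon, g, p)
  pts <- grid_points(g)
  far <- sqrt(rowSums(pts^2)) > p$lj_cutoff
  expect_true(all(f$values[far] == -0.848))
})

test_that("probe energy at the Lennard-Jones minimum matches the closed form", {
  p <- default_probe_params()
  rmin <- p$lj$rmin[p$lj$element == "C"]
  eps <- p$lj$eps[p$lj$element == "C"]
  expect_equal(dry_point_energy(c(rmin, 0, 0), one_carbon, p),
               -eps + p$delta_s, tolerance = 1e-12)
})

test_that("polar atoms add a non-negative inverted hydrogen-bond penalty", {
  p <- default_probe_params()
  oxy <- data.frame(elem = "O", x = 0, y = 0, z = 0)
  # same point, same LJ parameters, H-bond table emptied: pure-LJ reference
  p_nohb <- p
  p_nohb$hbond <- p$hbond[0, ]
  pt <- c(p$hbond$r0[p$hbond$element == "O"], 0, 0)
  e_full <- dry_point_energy(pt, oxy, p)
  e_lj <- dry_point_energy(pt, oxy, p_nohb)
  expect_gt(e_full, e_lj)
  # probe is neutral: partial charges never enter
  oxy_q <- cbind(oxy, charge = -0.8)
  expect_equal(dry_point_energy(pt, oxy_q, p), e_full)
  expect_error(dry_point_energy(c(0, 0, 0), data.frame(elem = "XX", x = 0, y = 0, z = 0), p),
               "unknown element|no Lennard-Jones")
})

test_that("field evaluation is spherically symmetric and clamps atomic cores", {
  p <- default_probe_params()
  g <- build_grid(one_carbon, spacing = 1, margin = 3)
  f <- compute_field(one_carbon, g, p)
  a <- array(f$values, dim = g$dim)
  expect_equal(a, a[7:1, , ], tolerance = 1e-12)
  expect_equal(a, a[, 7:1, ], tolerance = 1e-12)
  expect_equal(a, a[, , 7:1], tolerance = 1e-12)
  # the on-atom point is clamped, not infinite
  expect_equal(max(f$values), p$core_clamp)

  # empty structure: flat field at the entropy constant
  f0 <- compute_field(data.frame(elem = character(0), x = numeric(0),
                                 y = numeric(0), z = numeric(0)),
                      g, p)
  expect_true(all(f0$values == p$delta_s))
})

test_that("field reduction strategies behave as specified", {
  g <- list(origin = c(0, 0, 0), spacing = 1, dim = c(5L, 1L, 1L))
  class(g) <- "grid_spec"
  mkf <- function(v) {
    f <- list(grid = g, values = v, params = default_probe_params())
    class(f) <- "hie_field"
    f
  }
  f <- mkf(c(-3.0, -2.5, -0.5, 0.2, 1.0))
  expect_equal(aggregate_hie(f, "sum_below_cutoff", cutoff = -1), -5.5)
  expect_equal(aggregate_hie(mkf(c(-0.5, 0, 2)), "sum_below_cutoff", -1), 0)
  expect_equal(aggregate_hie(mkf(c(-4.2, -1, 3)), "min_point"), -4.2)
  expect_error(aggregate_hie(f, "weird"), "arg")

  # sum_below_cutoff is monotone non-increasing as the cutoff rises toward 0
  set.seed(21)
  fr <- mkf(runif(5, -4, 1))
  sums <- vapply(seq(-4, -0.1, by = 0.1), function(ct)
    aggregate_hie(fr, "sum_below_cutoff", ct), 1)
  expect_true(all(diff(sums) <= 1e-12))
})

test_that("a hydrophobic slab attracts the probe at its surface", {
  slab <- expand.grid(x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = 0)
  slab$elem <- "C"
  p <- default_probe_params()
  g <- build_grid(slab, spacing = 1, margin = 6)
  f <- compute_field(slab, g, p)
  pts <- grid_points(f$grid)
  best <- which.min(f$values)
  # brute-force minimum lies off the slab plane but within contact range
  expect_gt(abs(pts[best, 3]), 1)
  expect_lt(abs(pts[best, 3]), p$lj_cutoff)
  expect_lt(f$values[best], -1)
})

test_that("halving the grid spacing barely moves the field minimum", {
  p <- default_probe_params()
  g1 <- build_grid(one_carbon, spacing = 0.5, margin = 5)
  g2 <- build_grid(one_carbon, spacing = 0.25, margin = 5)
  m1 <- aggregate_hie(compute_field(one_carbon, g1, p), "min_point")
  m2 <- aggregate_hie(compute_field(one_carbon, g2, p), "min_point")
  expect_lt(abs(m1 - m2), 0.02)
})

test_that("HIE efficiency reproduces the printed hydrophobic ratios", {
  expect_equal(round(hie_efficiency(-38.9, 24), 1), -1.6)
  expect_equal(round(hie_efficiency(-24.3, 24), 1), -1.0)
  expect_equal(hie_efficiency(0, 10), 0)
  expect_error(hie_efficiency(-10, 0), "n_heavy")
})

test_that("fields serialize to OpenDX text", {
  g <- build_grid(one_carbon, spacing = 2, margin = 2)
  f <- compute_field(one_carbon, g)
  p <- tempfile(fileext = ".dx")
  write_dx(f, p)
  lines <- readLines(p)
  expect_match(lines[1], "gridpositions counts 3 3 3")
  expect_match(lines[7], "items 27")
})
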