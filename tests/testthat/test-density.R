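test_that("cube files round-trip losslessly", {
  orb <- gaussian_grid_orbital(sigma = c(0.8, 1.0, 1.2), n = 21)
  f <- tempfile(fileext = ".cube")
  write_cube(orb, f)
  back <- read_cube(f)
  expect_equal(back$shape, orb$shape)
  expect_lt(max(abs(back$values - orb$values)), 1e-6)
  expect_equal(back$origin, orb$origin, tolerance = 1e-5)
  unlink(f)
})

test_that("a hand-written 2x2x2 cube parses exactly", {
  f <- tempfile(fileext = ".cube")
  writeLines(c(
    "tiny cube", "by hand",
    "    0    0.000000    0.000000    0.000000",
    "    2    1.000000    0.000000    0.000000",
    "    2    0.000000    1.000000    0.000000",
    "    2    0.000000    0.000000    1.000000",
    " 1.00000e+00 2.00000e+00 3.00000e+00 4.00000e+00 5.00000e+00 6.00000e+00",
    " 7.00000e+00 8.00000e+00"), f)
  orb <- read_cube(f)
  expect_equal(orb$shape, c(2L, 2L, 2L))
  # cube order: x outer, z inner; stored [ix, iy, iz]
  expect_equal(orb$values[1, 1, 1], 1)
  expect_equal(orb$values[1, 1, 2], 2)
  expect_equal(orb$values[1, 2, 1], 3)
  expect_equal(orb$values[2, 1, 1], 5)
  expect_equal(orb$values[2, 2, 2], 8)
  # Bohr dialect: axes scale to Angstrom on read
  expect_equal(orb$axes[1, 1], chargemig:::BOHR_ANGSTROM, tolerance = 1e-9)
  unlink(f)
})

test_that("the Angstrom dialect (negative voxel counts) is honoured", {
  f_bohr <- tempfile(fileext = ".cube")
  f_ang <- tempfile(fileext = ".cube")
  vals <- " 1.0 2.0 3.0 4.0 5.0 6.0\n 7.0 8.0"
  hdr <- function(n, step) c(
    "dialect test", "",
    "    0    0.0    0.0    0.0",
    sprintf("   %2d    %f    0.0    0.0", n, step),
    sprintf("   %2d    0.0    %f    0.0", abs(n), step),
    sprintf("   %2d    0.0    0.0    %f", abs(n), step))
  b <- 1 / chargemig:::BOHR_ANGSTROM # 1 Angstrom in Bohr
  writeLines(c(hdr(2, b), vals), f_bohr)
  writeLines(c(hdr(-2, 1), vals), f_ang)
  ob <- read_cube(f_bohr)
  oa <- read_cube(f_ang)
  # both describe a 1-Angstrom grid: identical integrals (to the 6-decimal
  # precision of the written header)
  expect_equal(ob$normalization, oa$normalization, tolerance = 1e-5)
  expect_equal(ob$axes, oa$axes, tolerance = 1e-5)
  unlink(c(f_bohr, f_ang))
})

test_that("malformed cubes raise parse errors", {
  f <- tempfile(fileext = ".cube")
  writeLines(c("a", "b", "oops not numbers here x"), f)
  expect_error(read_cube(f), class = "chargemig_parse_error")
  writeLines(c("a", "b",
               "    0    0.0    0.0    0.0",
               "    2    1.0    0.0    0.0",
               "    2    0.0    1.0    0.0",
               "    2    0.0    0.0    1.0",
               " 1.0 2.0 3.0"), f)
  expect_error(read_cube(f), class = "chargemig_parse_error")
  unlink(f)
})

test_that("out-of-slab fraction matches the analytic Gaussian integral", {
  # voxel-centre membership has a boundary error proportional to the
  # z-spacing, so a fine anisotropic grid along the slab normal is needed
  for (sz in c(2.5, 3)) {
    orb <- gaussian_grid_orbital(sigma = c(1, 1, sz), half_extent = 6,
                                 n = c(25, 25, 4001))
    q <- out_of_plane_density(list(orb), 1, plane_normal = c(0, 0, 1),
                              plane_point = c(0, 0, 0), distance = 3)
    analytic <- chargemig:::erfc(3 / (sz * sqrt(2)))
    expect_equal(q$q_out, analytic, tolerance = 0.005)
  }
})

test_that("slab integration is normalised, linear and monotone", {
  # two Gaussians on one common grid
  common_gaussian <- function(sz) {
    n <- 61
    origin <- c(-9, -9, -12)
    axes <- diag(c(18, 18, 24) / (n - 1))
    g1 <- function(x, s) exp(-x^2 / (4 * s^2)) / (2 * pi * s^2)^0.25
    xs <- origin[1] + (seq_len(n) - 1) * axes[1, 1]
    zs <- origin[3] + (seq_len(n) - 1) * axes[3, 3]
    vals <- outer(outer(g1(xs, 1), g1(xs, 1)), g1(zs, sz))
    dim(vals) <- c(n, n, n)
    grid_orbital(origin, axes, vals)
  }
  o1 <- common_gaussian(1)
  o2 <- common_gaussian(2)
  # full space: distance 0 recovers the total occupation (plane shifted off
  # the grid nodes: membership is strict, so voxel centres exactly on the
  # plane would otherwise be excluded)
  q_all <- out_of_plane_density(list(o1, o2), c(0.7, 1.3), distance = 0,
                                plane_point = c(0, 0, 0.123))
  expect_equal(q_all$q_out, 2.0, tolerance = 0.01)
  # orbital well inside the slab contributes nothing
  tight <- gaussian_grid_orbital(sigma = c(0.5, 0.5, 0.3), n = 41)
  q0 <- out_of_plane_density(list(tight), 1, distance = 3)
  expect_lt(q0$q_out, 1e-8)
  # linearity in occupations
  qa <- out_of_plane_density(list(o2), 1, distance = 2)$q_out
  qb <- out_of_plane_density(list(o2), 2.5, distance = 2)$q_out
  expect_equal(qb, 2.5 * qa, tolerance = 1e-12)
  # monotone nonincreasing in the distance
  qd <- vapply(c(0, 1, 2, 3, 4), function(d)
    out_of_plane_density(list(o2), 1, distance = d)$q_out, numeric(1))
  expect_true(all(diff(qd) <= 0))
  # time-series input
  occ <- matrix(c(1, 0.5, 0.2, 0, 0.5, 0.8), 3, 2)
  qt <- out_of_plane_density(list(o1, o2), occ, distance = 2,
                             times = c(0, 1, 2))
  expect_equal(nrow(qt), 3)
  expect_equal(qt$time_fs, c(0, 1, 2))
})

test_that("grid refinement changes the slab integral by less than 1%", {
  oc <- gaussian_grid_orbital(sigma = c(1, 1, 1.8), half_extent = 5,
                              n = c(21, 21, 2401))
  of <- gaussian_grid_orbital(sigma = c(1, 1, 1.8), half_extent = 5,
                              n = c(21, 21, 4801))
  qc <- out_of_plane_density(list(oc), 1, distance = 3)$q_out
  qf <- out_of_plane_density(list(of), 1, distance = 3)$q_out
  expect_lt(abs(qc - qf) / qf, 0.01)
})

test_that("plane fitting and input validation work", {
  set.seed(1)
  pts <- cbind(rnorm(30), rnorm(30), rnorm(30, sd = 0.01))
  pl <- best_fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-3)
  o1 <- gaussian_grid_orbital(n = 21)
  o2 <- gaussian_grid_orbital(n = 31)
  expect_error(out_of_plane_density(list(o1, o2), c(1, 1)),
               class = "chargemig_invalid")
  expect_error(out_of_plane_density(list(o1), 1, plane_normal = c(0, 0, 0)),
               class = "chargemig_invalid")
  expect_error(grid_orbital(c(0, 0, 0), diag(3), array(1, c(2, 2, 2)),
                            normalization = 99), class = "chargemig_invalid")
})
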