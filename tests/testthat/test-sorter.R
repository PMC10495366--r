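test_that("critical angle grows with load and respects the clamp", {
  expect_equal(critical_angle(0, dev0, cst0, flw0), 0)
  expect_error(critical_angle(-1, dev0, cst0, flw0), "n must be")
  th <- critical_angle(0:60, dev0, cst0, flw0)
  expect_true(all(diff(th) >= 0))
  # clamp saturates at 90 degrees once F_m exceeds F_d
  expect_equal(critical_angle(1000, dev0, cst0, flw0), 90)
  expect_error(critical_angle(4, dev0, physical_constants(), flw0),
               "uncalibrated")
})

test_that("minimum deflectable load follows the sine law from the anchor", {
  expect_identical(min_mnp_count(3, dev0, cst0, flw0), 4L)
  # ceil(4 sin5/sin3) = ceil(6.66), ceil(4 sin10/sin3) = ceil(13.27)
  expect_identical(min_mnp_count(5, dev0, cst0, flw0), 7L)
  expect_identical(min_mnp_count(10, dev0, cst0, flw0), 14L)
  expect_error(min_mnp_count(0, dev0, cst0, flw0), "theta")
  expect_error(min_mnp_count(90, dev0, cst0, flw0), "theta")
  # self-consistency with critical_angle at every angle on a grid
  for (th in c(1, 2.5, 3, 4, 7, 12, 20)) {
    n <- min_mnp_count(th, dev0, cst0, flw0)
    expect_gte(critical_angle(n, dev0, cst0, flw0), th - 1e-9)
    if (n > 1) expect_lt(critical_angle(n - 1, dev0, cst0, flw0), th)
  }
})

test_that("settling time follows the cubic closed form", {
  expect_equal(settle_time(dev0$z_settle, 5, dev0, cst0, flw0), 0)
  expect_identical(settle_time(10e-6, 0, dev0, cst0, flw0), Inf)
  t1 <- settle_time(25e-6, 3, dev0, cst0, flw0)
  t2 <- settle_time(25e-6, 6, dev0, cst0, flw0)
  expect_equal(t1 / t2, 2, tolerance = 1e-12)
  # linear in radius
  ta <- settle_time(25e-6, 3, dev0, cst0, flw0, radius = 40e-9)
  tb <- settle_time(25e-6, 3, dev0, cst0, flw0, radius = 80e-9)
  expect_equal(tb / ta, 2, tolerance = 1e-12)
  expect_error(settle_time(40e-6, 3, dev0, cst0, flw0), "z0")
  # independent check of the closed form: numeric quadrature of 1/v_z(z)
  vz <- function(z) cst0$vertical_coupling * 3 * cst0$force_scale_A /
    ((z + dev0$guide_gap)^2 * 6 * pi * cst0$viscosity * cst0$reference_radius)
  t_num <- stats::integrate(function(z) 1 / vz(z), dev0$z_settle, 25e-6)$value
  expect_equal(settle_time(25e-6, 3, dev0, cst0, flw0), t_num,
               tolerance = 1e-8)
})

test_that("the design loads 4, 10, 20 route to low, medium, high", {
  v <- function(n) list(mnp_count = n, y0 = 0, z0 = 5e-6, radius = 50e-9)
  expect_identical(route(v(4), dev0, cst0, flw0), "low")
  expect_identical(route(v(10), dev0, cst0, flw0), "medium")
  expect_identical(route(v(20), dev0, cst0, flw0), "high")
  expect_identical(route(v(3), dev0, cst0, flw0), "negative")
  expect_identical(route(v(0), dev0, cst0, flw0), "negative")
  expect_error(route(list(mnp_count = 4), dev0, cst0, flw0), "z0")
})

test_that("vesicles that cannot settle in time are not deflected", {
  tall <- build_device(list(device = list(channel_height_um = 500)))
  ft <- flow_condition(200, tall$device)
  # n = 8 settles easily at the default height -> medium
  expect_identical(route(list(mnp_count = 8, z0 = 25e-6, radius = 50e-9),
                         dev0, cst0, flw0), "medium")
  # same load entering a 500 um channel at the ceiling runs out of length
  expect_gt(settle_time(500e-6, 8, tall$device, cst0, ft),
            residence_time(tall$device, ft))
  expect_identical(route(list(mnp_count = 8, z0 = 500e-6, radius = 50e-9),
                         tall$device, cst0, ft), "negative")
})

test_that("outlet rank is monotone in MNP load at fixed conditions", {
  lev <- c("negative", "low", "medium", "high")
  out <- vapply(0:40, function(n) {
    route(list(mnp_count = n, y0 = 0, z0 = 8e-6, radius = 50e-9),
          dev0, cst0, flw0)
  }, character(1))
  rank <- match(out, lev)
  expect_true(all(diff(rank) >= 0))
})

test_that("routing a population conserves counts and fills outlets", {
  pop <- sample_population(make_fixture("wt_h1975", 2e4, seed = 6), dev0, cst0)
  res <- run_experiment(pop, dev0, cst0, flw0)
  expect_identical(sum(unlist(res$counts[c("negative", "low", "medium", "high")])),
                   nrow(pop))
  expect_false(anyNA(res$population$outlet))
  expect_true(all(res$population$outlet %in% dev0$outlet_labels))
  expect_error(run_experiment(pop[0, ], dev0, cst0, flw0), "empty population")
})

test_that("crosstalk reassigns to adjacent outlets only, reproducibly", {
  pop <- sample_population(make_fixture("wt_h1975", 5e3, seed = 8), dev0, cst0)
  clean <- route_population(pop, dev0, cst0, flw0)
  noisy1 <- route_population(pop, dev0, cst0, flw0, crosstalk = 0.3, seed = 99)
  noisy2 <- route_population(pop, dev0, cst0, flw0, crosstalk = 0.3, seed = 99)
  expect_identical(noisy1$outlet, noisy2$outlet)
  lev <- c("negative", "low", "medium", "high")
  shift <- abs(match(noisy1$outlet, lev) - match(clean$outlet, lev))
  expect_true(all(shift <= 1))
  expect_gt(mean(shift == 1), 0.1)
})

test_that("sorting output is deterministic under a fixed seed", {
  a <- run_experiment(make_fixture("h460_mid", 1e4, seed = 10), dev0, cst0,
                      flw0, seed = 10)
  b <- run_experiment(make_fixture("h460_mid", 1e4, seed = 10), dev0, cst0,
                      flw0, seed = 10)
  expect_identical(a$counts, b$counts)
})
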