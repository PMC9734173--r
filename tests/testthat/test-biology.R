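dom <- tiny_domain()
zones <- build_sensory_zones(dom, radius_km = 4)

test_that("pelagic survival follows the exponential mortality closed form", {
  expect_equal(pelagic_survival(0), 1)
  expect_equal(pelagic_survival(1), 0.82)
  expect_equal(pelagic_survival(25), 0.82^25)
  expect_equal(pelagic_survival(12.5, 0.1), 0.9^12.5)
  expect_error(pelagic_survival(-1), "non-negative")
  # nonincreasing in age
  ages <- seq(0, 25, by = 0.5)
  expect_true(all(diff(pelagic_survival(ages)) < 0))
})

test_that("stochastic-removal survival matches the deterministic weight", {
  n <- 1e5
  sim <- simulate_survival(n, days = 25, daily_mortality = 0.18, seed = 99)
  expect_lt(abs(sim$fraction - 0.82^25), 3 * sim$se)
})

test_that("sensory-zone membership respects the 4 km buffer", {
  # a single isolated reef, so distances are unambiguous
  r <- dom$reefs[1, ]
  z1 <- build_sensory_zones(r, radius_km = 4)
  expect_false(is.na(zone_contains(z1, r$xmax + 3.9, (r$ymin + r$ymax) / 2)))
  expect_true(is.na(zone_contains(z1, r$xmax + 4.1, (r$ymin + r$ymax) / 2)))
  # corner distance is Euclidean (rounded-corner buffer)
  expect_true(is.na(zone_contains(z1, r$xmax + 3, r$ymax + 3)))  # 4.24 km
  expect_false(is.na(zone_contains(z1, r$xmax + 2.5, r$ymax + 2.5)))
  expect_error(build_sensory_zones(dom, radius_km = 0))
})

test_that("zone area matches the rectangle-buffer closed form", {
  pointy <- data.frame(reef_id = 1L, region_id = 1L,
                       xmin = 50, xmax = 50, ymin = 50, ymax = 50)
  zp <- build_sensory_zones(pointy, radius_km = 4)
  expect_equal(zone_area(zp), pi * 16, tolerance = 1e-12)  # ~50.27 km^2
  sq <- data.frame(reef_id = 1L, region_id = 1L,
                   xmin = 0, xmax = 4, ymin = 0, ymax = 4)
  expect_equal(zone_area(build_sensory_zones(sq, 4)), 16 + 64 + pi * 16)
  bad <- data.frame(reef_id = 1L, region_id = 1L,
                    xmin = 2, xmax = 1, ymin = 0, ymax = 1)
  expect_error(build_sensory_zones(bad, 4), "degenerate")
})

test_that("settlement takes first zone contact after competency, with weight", {
  # straight northward path reaching region 1's reefs around age 15 days
  r1 <- dom$reefs[dom$reefs$region_id == 1L, ][1, ]
  times <- seq(0, 25 * 24, by = 12)
  path <- cbind(times,
                x = (r1$xmin + r1$xmax) / 2,
                y = (r1$ymin + r1$ymax) / 2 - 50 + 0.125 * times)
  traj <- list(path = path, status = "pelagic")
  rec <- evaluate_settlement(traj, zones, competency_start = 0,
                             source_region = 4L)
  expect_identical(rec$settle_region, r1$region_id)
  expect_equal(rec$weight,
               pelagic_survival(rec$age_days) * 0.87)
  # with competency at 20 d the same path settles later (or not at all)
  rec20 <- evaluate_settlement(traj, zones, competency_start = 20,
                               source_region = 4L)
  if (!is.null(rec20)) expect_gte(rec20$age_days, 20)
  # a path that never nears a reef is excluded
  far <- list(path = cbind(times, x = 90, y = 5), status = "pelagic")
  expect_null(evaluate_settlement(far, zones))
  # lost particles are excluded
  expect_null(evaluate_settlement(list(path = path, status = "lost"), zones))
})

test_that("settlement at the full PLD carries the compounded survival weight", {
  r1 <- dom$reefs[1, ]
  path <- cbind(c(0, 25 * 24), x = c(90, (r1$xmin + r1$xmax) / 2),
                y = c(5, (r1$ymin + r1$ymax) / 2))
  rec <- evaluate_settlement(list(path = path, status = "pelagic"), zones,
                             competency_start = 25)
  expect_equal(rec$age_days, 25)
  expect_equal(rec$weight, 0.82^25 * 0.87)     # ~6.09e-3
  expect_lt(rec$weight, 0.87)                  # settlement survival bound
})

test_that("overlapping zones resolve to the nearest reef, lower id on ties", {
  two <- data.frame(reef_id = c(1L, 2L), region_id = c(1L, 2L),
                    xmin = c(10, 20), xmax = c(12, 22),
                    ymin = c(0, 0), ymax = c(2, 2))
  z <- build_sensory_zones(two, radius_km = 6)
  expect_identical(zone_contains(z, 13, 1), 1L)   # 1 km vs 7 km
  expect_identical(zone_contains(z, 19, 1), 2L)   # 7 km vs 1 km
  expect_identical(zone_contains(z, 16, 1), 1L)   # exact tie -> lower id
})

test_that("a larger sensory radius never loses settlers", {
  f <- generate_velocity_field(dom, 0, seed = 13,
                               season = season_config(days = 27))
  sched <- make_release_schedule(dom, rate = 2, n_days = 1)
  n_settled <- vapply(c(2, 4, 8), function(r) {
    tr <- track_particles(sched, f, zones = build_sensory_zones(dom, r),
                          competency_start = 20, dt = 1)
    sum(tr$status == "settled")
  }, numeric(1))
  expect_true(all(diff(n_settled) >= 0))
})

test_that("with mortality disabled every settler has weight exactly 1", {
  f <- generate_velocity_field(dom, 0, seed = 13,
                               season = season_config(days = 27))
  sched <- make_release_schedule(dom, rate = 2, n_days = 1)
  tr <- track_particles(sched, f, zones = zones, competency_start = 20, dt = 1)
  rec <- settlement_records(tr, settlement_mortality = 0,
                            daily_mortality = 0)
  expect_true(nrow(rec) > 0)
  expect_true(all(rec$weight == 1))
  # default mortality: weights bounded by the settlement survival factor
  rec2 <- settlement_records(tr)
  expect_true(all(rec2$weight > 0 & rec2$weight <= 0.87))
  expect_true(all(rec2$age_days <= 25))
})
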