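dom <- tiny_domain()

test_that("release schedule arithmetic matches rate x cells x days", {
  sched <- make_release_schedule(dom, rate = 100, n_days = 2)
  # tiny domain has 8 seed cells
  expect_equal(sum(sched$count), 100 * 8 * 2)
  sub <- make_release_schedule(dom, rate = 100, n_days = 1)
  expect_equal(sum(sub$count[sub$cell_id %in% 1:3]), 300)
  empty <- make_release_schedule(dom, rate = 0)
  expect_identical(nrow(empty), 0L)
  full <- make_release_schedule(generate_domain(domain_config(), 1),
                                rate = 100, n_days = 92)
  expect_equal(sum(full$count), 1297200)  # the full study scale
})

test_that("depth-by-age schedule maps day 1 to 1 m, 2-20 to 3 m, 21-25 to 6 m", {
  expect_equal(depth_for_age(0.5), 1)
  expect_equal(depth_for_age(0), 1)
  expect_equal(depth_for_age(1), 3)
  expect_equal(depth_for_age(10), 3)
  expect_equal(depth_for_age(20), 6)
  expect_equal(depth_for_age(23), 6)
  expect_equal(depth_for_age(25), 6)
  expect_error(depth_for_age(-0.1), "\\[0, 25\\]")
  expect_error(depth_for_age(26), "\\[0, 25\\]")
})

test_that("one RK4 step in a constant field gives the exact displacement", {
  f <- uniform_field(dom, u = 0.1, v = 0)
  p <- rk4_step(f, c(40, 100), time = 0, dt = 1, depth_layer = 1)
  expect_equal(p, c(40.36, 100))               # 0.1 m/s over 3600 s
  f0 <- uniform_field(dom, 0, 0)
  expect_equal(rk4_step(f0, c(40, 100), 0, 1), c(40, 100))
})

test_that("RK4 closes a solid-body orbit and converges ~ O(dt^4)", {
  period <- 240                                 # hours
  omega <- 2 * pi / period
  f <- rotation_field(dom, omega, days = 11)
  start <- c(48 + 20, 100)                      # radius 20 km about centre
  run <- function(nsteps) {
    dt <- period / nsteps
    p <- start
    for (s in seq_len(nsteps)) p <- rk4_step(f, p, (s - 1) * dt, dt)
    sqrt(sum((p - start)^2))
  }
  expect_lt(run(100), 1e-3 * 20)                # back to start after a period
  errs <- vapply(c(16, 32, 64, 128), run, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 8))                  # ~16x per halving for O(dt^4)
})

test_that("a uniform northward drift carries every particle 216 km in 25 days", {
  tall <- generate_domain(domain_config(extent_x = 96, extent_y = 400,
                                        sectors = c("northern", "southern"),
                                        regions_per_sector = c(2L, 2L),
                                        reefs_per_region = 2L),
                          seed = 1)
  f <- uniform_field(tall, u = 0, v = 0.1, days = 27)
  # release from the southernmost region so the drift stays in the domain
  cells <- which(tall$seed_cells$region_id == 4L)
  sched <- one_particle_schedule(tall, cell = cells[1])
  sched <- rbind(sched, one_particle_schedule(tall, cell = cells[2]))
  attr(sched, "seed_cells") <- tall$seed_cells[cells, ]
  class(sched) <- c("release_schedule", "data.frame")
  tr <- track_particles(sched, f, dt = 0.5)
  expect_true(all(tr$status == "pelagic"))
  rel <- larvalconn:::release_positions(sched)
  expect_equal(tr$final_y - rel$y, rep(0.1 * 3.6 * 600, nrow(tr)))
})

test_that("particles crossing the open boundary are lost, and counts conserve", {
  f <- uniform_field(dom, u = 0, v = -0.3, days = 27)   # 648 km poleward
  sched <- make_release_schedule(dom, rate = 3, n_days = 1)
  zones <- build_sensory_zones(dom, 4)
  tr <- track_particles(sched, f, dt = 0.5, zones = zones,
                        competency_start = 20)
  expect_true(any(tr$status == "lost"))
  expect_equal(nrow(tr), sum(tr$status == "settled") +
                 sum(tr$status == "pelagic") + sum(tr$status == "lost"))
  expect_true(all(is.na(tr$settle_region[tr$status != "settled"])))
})

test_that("tracking is deterministic and zero-diffusion runs are seed-independent", {
  f <- generate_velocity_field(dom, -10, seed = 3,
                               season = season_config(days = 27))
  sched <- make_release_schedule(dom, rate = 2, n_days = 1)
  a <- track_particles(sched, f, dt = 1, seed = 1)
  b <- track_particles(sched, f, dt = 1, seed = 1)
  c <- track_particles(sched, f, dt = 1, seed = 77)
  expect_identical(a, b)
  expect_identical(a, c)                        # no diffusion: seed-free
  d1 <- track_particles(sched, f, dt = 1, diffusion = 0.5, seed = 5)
  d2 <- track_particles(sched, f, dt = 1, diffusion = 0.5, seed = 5)
  d3 <- track_particles(sched, f, dt = 1, diffusion = 0.5, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("the compiled tracker matches the pure-R RK4 reference", {
  f <- generate_velocity_field(dom, -12, seed = 21,
                               season = season_config(days = 27))
  sched <- make_release_schedule(dom, rate = 1, n_days = 1)
  tr <- track_particles(sched, f, dt = 0.5, record = TRUE)
  rel <- larvalconn:::release_positions(sched)
  for (p in c(1L, 4L, 8L)) {
    ref <- larvalconn:::advect_reference(f, rel$x[p], rel$y[p],
                                         rel$release_hour[p], dt = 0.5)
    got <- attr(tr, "trajectories")[[p]]
    n <- min(nrow(ref$path), nrow(got))
    expect_equal(got[seq_len(n), ], ref$path[seq_len(n), ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a schedule outrunning the velocity coverage is rejected", {
  f <- uniform_field(dom, 0, 0, days = 20)      # < release + 25 d PLD
  sched <- make_release_schedule(dom, rate = 1, n_days = 1)
  expect_error(track_particles(sched, f), "coverage ends")
})
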