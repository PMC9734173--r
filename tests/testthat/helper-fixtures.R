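# small shared fixtures, built in code

tiny_domain <- function(seed = 1) {
  generate_domain(domain_config(extent_x = 96, extent_y = 200, dx = 8, dy = 8,
                                sectors = c("northern", "southern"),
                                regions_per_sector = c(2L, 2L),
                                reefs_per_region = 2L,
                                y_margin = 20),
                  seed = seed)
}

# spatially uniform, time-constant field over a tiny domain
uniform_field <- function(dom, u = 0, v = 0, days = 30) {
  f <- generate_velocity_field(dom, index_value = 0,
                               season = season_config(days = days,
                                                      jet_v0 = 0, jet_gamma = 0,
                                                      tide_amp = 0, eddy_amp = 0,
                                                      intrusion = 0,
                                                      taper_width = 1e-6,
                                                      shear = c(1, 1, 1)),
                               seed = 1)
  f$u[] <- u
  f$v[] <- v
  # keep land at zero only when explicitly asked for; uniform tests use
  # an all-water mask so constant-field arithmetic is exact
  f$land_mask[] <- FALSE
  f
}

# solid-body rotation u = -w (y - yc), v = w (x - xc) about the grid centre,
# time-constant; linear in space so bilinear interpolation is exact
rotation_field <- function(dom, omega_per_h, days = 30) {
  f <- uniform_field(dom, 0, 0, days = days)
  xc <- mean(range(f$x)); yc <- mean(range(f$y))
  U <- outer(f$x, f$y, function(x, y) -omega_per_h * (y - yc)) / 3.6
  V <- outer(f$x, f$y, function(x, y)  omega_per_h * (x - xc)) / 3.6
  for (d in 1:3) for (t in seq_along(f$time)) {
    f$u[, , d, t] <- U
    f$v[, , d, t] <- V
  }
  f
}

# single-particle schedule releasing at a given cell
one_particle_schedule <- function(dom, cell = 1L, release_hour = 0) {
  sc <- dom$seed_cells[cell, , drop = FALSE]
  sched <- data.frame(cell_id = sc$cell_id, reef_id = sc$reef_id,
                      region_id = sc$region_id, release_hour = release_hour,
                      count = 1L)
  structure(sched, rate = 1L, n_days = 1L,
            region_ids = dom$regions$region_id, seed_cells = sc,
            class = c("release_schedule", "data.frame"))
}
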