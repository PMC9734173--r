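#' Build a uniform larval release schedule
#'
#' One release per seed cell per day over the release window, at a constant
#' rate (default 100 particles per cell per day, the full study rate; desk
#' runs use a reduced rate). Release positions are spread deterministically
#' within each seed cell by a low-discrepancy sequence, so zero-diffusion
#' runs are independent of the RNG seed.
#'
#' @param domain a `domain`.
#' @param rate particles per cell per day (non-negative integer; 0 gives an
#'   empty schedule).
#' @param n_days number of daily release days (default 92: 1 October through
#'   31 December).
#' @param start_hour hour (since window start) of the first daily release.
#' @return object of class `release_schedule`: data frame with one row per
#'   (cell, day): `cell_id`, `reef_id`, `region_id`, `release_hour`, `count`;
#'   attributes `rate`, `n_days`, `domain_regions`.
#' @examples
#' dom <- generate_domain(domain_config(), seed = 1)
#' sched <- make_release_schedule(dom, rate = 100, n_days = 92)
#' sum(sched$count)  # 141 * 92 * 100 = 1297200
#' @export
make_release_schedule <- function(domain, rate = 100, n_days = 92,
                                  start_hour = 0) {
  stopifnot(inherits(domain, "domain"), rate >= 0, n_days >= 1)
  rate <- as.integer(rate)
  sc <- domain$seed_cells
  if (rate == 0L || nrow(sc) == 0L) {
    sched <- data.frame(cell_id = integer(), reef_id = integer(),
                        region_id = integer(), release_hour = numeric(),
                        count = integer())
  } else {
    days <- rep(seq_len(n_days), each = nrow(sc))
    sched <- data.frame(cell_id = rep(sc$cell_id, n_days),
                        reef_id = rep(sc$reef_id, n_days),
                        region_id = rep(sc$region_id, n_days),
                        release_hour = (days - 1) * 24 + start_hour,
                        count = rate)
  }
  structure(sched, rate = rate, n_days = n_days,
            region_ids = domain$regions$region_id,
            seed_cells = sc, class = c("release_schedule", "data.frame"))
}

#' Depth layer for a larval age
#'
#' The behavioural depth-by-age schedule: ages in day 1 (i.e. `[0, 1)` days)
#' at 1 m, days 2-20 (`[1, 20)`) at 3 m, and days 21-25 (`[20, 25]`) at 6 m.
#'
#' @param age age in days, in `[0, 25]`; vectorized.
#' @return depth in metres (1, 3 or 6).
#' @export
depth_for_age <- function(age) {
  if (any(age < 0 | age > 25)) stop("age must lie in [0, 25] days")
  ifelse(age < 1, 1, ifelse(age < 20, 3, 6))
}

#' One classical fourth-order Runge-Kutta advection step
#'
#' Advances a position through the interpolated velocity field over `dt`
#' hours at a fixed depth layer. Velocities (m/s) are converted to km/h
#' internally, so a uniform 0.1 m/s current moves a particle 0.36 km in one
#' hour.
#'
#' @param field a `velocity_field`.
#' @param position numeric length-2 `(x, y)` in km.
#' @param time hours since window start.
#' @param dt step length in hours.
#' @param depth_layer depth in metres (one of `field$depths`).
#' @return numeric length-2 updated position. Errors if any of the four
#'   stage evaluations falls outside the grid hull or time span.
#' @export
rk4_step <- function(field, position, time, dt, depth_layer = 1) {
  stopifnot(dt > 0, length(position) == 2)
  vel <- function(p, t) {
    w <- interpolate_velocity(field, p[1], p[2], t, depth_layer)
    c(w$u, w$v) * 3.6                       # m/s -> km/h
  }
  k1 <- vel(position, time)
  k2 <- vel(position + dt / 2 * k1, time + dt / 2)
  k3 <- vel(position + dt / 2 * k2, time + dt / 2)
  k4 <- vel(position + dt * k3, time + dt)
  position + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# deterministic within-cell release offsets (Halton pairs), one per particle
release_positions <- function(schedule) {
  sc <- attr(schedule, "seed_cells")
  counts <- schedule$count
  n <- sum(counts)
  if (n == 0)
    return(data.frame(x = numeric(), y = numeric(), release_hour = numeric(),
                      reef_id = integer(), region_id = integer()))
  row <- rep(seq_len(nrow(schedule)), counts)
  k <- sequence(counts)                      # particle index within release
  cells <- sc[match(schedule$cell_id[row], sc$cell_id), ]
  maxc <- max(counts)
  h2 <- van_der_corput(maxc, 2L); h3 <- van_der_corput(maxc, 3L)
  data.frame(x = cells$x + (h2[k] - 0.5) * 2 * cells$half * 0.98,
             y = cells$y + (h3[k] - 0.5) * 2 * cells$half * 0.98,
             release_hour = schedule$release_hour[row],
             reef_id = schedule$reef_id[row],
             region_id = schedule$region_id[row])
}

#' Track particles through a velocity field
#'
#' Releases every particle of the schedule and advects it with RK4 (step
#' `dt` hours, depth layer switching by age per [depth_for_age()]) until
#' settlement, loss through the open boundary, or the end of the 25-day
#' pelagic larval duration. Velocities are zero on land and interpolation
#' tapers to zero near the coast, so particles stall rather than beach; a
#' step that would land a particle on a land cell is undone (the particle
#' stays put for that step). Optional horizontal diffusion adds a seeded
#' random-walk displacement of standard deviation `sqrt(2 K dt)` per axis.
#'
#' If `zones` is supplied, settlement is evaluated in-loop: the first state
#' (including release) at age >= `competency_start` within any sensory zone
#' settles the particle to the zone's reef (nearest reef boundary wins,
#' lower reef id on ties).
#'
#' @param schedule a [make_release_schedule()] object.
#' @param field a `velocity_field` covering every release plus the full PLD.
#' @param dt integration step in hours (default 0.5).
#' @param diffusion horizontal diffusivity K (km^2/h), default 0.
#' @param seed RNG seed (used only when `diffusion > 0`).
#' @param zones optional [build_sensory_zones()] object.
#' @param competency_start age (days) from which settlement is possible.
#' @param pld pelagic larval duration (days).
#' @param record if TRUE, keep full per-step trajectories (memory-heavy;
#'   desk scale only).
#' @return object of class `trajectory_set`: data frame with one row per
#'   particle (`particle_id`, `reef_id`, `region_id`, `release_hour`,
#'   `status` in pelagic/settled/lost, `settle_reef`, `settle_region`,
#'   `settle_age_days`, `final_x`, `final_y`) plus, when `record = TRUE`, a
#'   `trajectories` attribute (list of step x (time, x, y) matrices).
#' @export
track_particles <- function(schedule, field, dt = 0.5, diffusion = 0,
                            seed = 1L, zones = NULL, competency_start = 0,
                            pld = 25, record = FALSE) {
  stopifnot(inherits(schedule, "release_schedule"),
            inherits(field, "velocity_field"), dt > 0, diffusion >= 0)
  if (24 %% dt != 0) stop("dt must divide 24 h")
  tmax <- field$time[length(field$time)]
  if (nrow(schedule) > 0 && max(schedule$release_hour) + pld * 24 > tmax)
    stop("velocity coverage ends before the last particle's PLD: need ",
         max(schedule$release_hour) + pld * 24, " h, field spans ", tmax, " h")
  rel <- release_positions(schedule)
  np <- nrow(rel)
  if (np == 0) {
    out <- data.frame(particle_id = integer(), reef_id = integer(),
                      region_id = integer(), release_hour = numeric(),
                      status = character(), settle_reef = integer(),
                      settle_region = integer(), settle_age_days = numeric(),
                      final_x = numeric(), final_y = numeric())
    return(structure(out, class = c("trajectory_set", "data.frame")))
  }
  do_settle <- !is.null(zones)
  if (do_settle) stopifnot(inherits(zones, "sensory_zones"))
  reefs <- if (do_settle)
    as.matrix(zones$reefs[, c("xmin", "xmax", "ymin", "ymax")])
  else matrix(0, 0, 4)
  reef_region <- if (do_settle) as.integer(zones$reefs$region_id) else integer()
  set.seed(seed)
  res <- .track_cpp(field$u, field$v, dim(field$u),
                    field$x[1], field$x[2] - field$x[1],
                    field$y[1], field$y[2] - field$y[1],
                    field$time[1], field$time[2] - field$time[1],
                    as.integer(field$land_mask),
                    rel$x, rel$y, rel$release_hour,
                    dt, pld * 24, c(1, 20) * 24,
                    diffusion, reefs, reef_region,
                    if (do_settle) zones$radius_km else 0,
                    competency_start * 24, do_settle, record)
  out <- data.frame(particle_id = seq_len(np), reef_id = rel$reef_id,
                    region_id = rel$region_id,
                    release_hour = rel$release_hour,
                    status = c("pelagic", "settled", "lost")[res$status + 1L],
                    settle_reef = res$settle_reef,
                    settle_region = res$settle_region,
                    settle_age_days = res$settle_age_days,
                    final_x = res$final_x, final_y = res$final_y)
  structure(out, trajectories = res$trajectories, dt = dt,
            competency_start = competency_start, pld = pld,
            class = c("trajectory_set", "data.frame"))
}

# pure-R reference tracker (single particle, no diffusion, no settlement):
# used as an independent check of the compiled loop
advect_reference <- function(field, x, y, release_hour, dt = 0.5, pld = 25) {
  t <- release_hour
  nsteps <- round(pld * 24 / dt)
  path <- matrix(NA_real_, nsteps + 1, 3)
  path[1, ] <- c(t, x, y)
  for (s in seq_len(nsteps)) {
    age_h <- (s - 1) * dt
    layer <- depth_for_age(min(age_h / 24, 25))
    p <- tryCatch(rk4_step(field, c(x, y), t, dt, layer), error = function(e) NULL)
    if (is.null(p)) return(list(path = path[seq_len(s), , drop = FALSE],
                                status = "lost"))
    # land snap-back, mirroring the compiled tracker
    ix <- round((p[1] - field$x[1]) / (field$x[2] - field$x[1])) + 1
    iy <- round((p[2] - field$y[1]) / (field$y[2] - field$y[1])) + 1
    ix <- min(max(ix, 1), length(field$x)); iy <- min(max(iy, 1), length(field$y))
    if (field$land_mask[ix, iy]) p <- c(x, y)
    x <- p[1]; y <- p[2]; t <- t + dt
    path[s + 1, ] <- c(t, x, y)
  }
  list(path = path, status = "pelagic")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set: ", nrow(x), " particles (",
      sum(x$status == "settled"), " settled, ",
      sum(x$status == "pelagic"), " pelagic at PLD end, ",
      sum(x$status == "lost"), " lost)\n", sep = "")
  invisible(x)
}
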