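#' Season configuration for the synthetic ocean
#'
#' Parameters of the climate-index-forced flow model. The along-shelf
#' velocity is
#' \deqn{v(x, y, t) = s_d \, r(x) \left[ (v_0 + \gamma I)\, p(x)
#'       + A_T \sin(2\pi t / T) + v_{eddy}(x, y, t) \right]}
#' and the across-shelf velocity
#' \deqn{u(x, y, t) = s_d \, r(x) \left[ -\eta |I|\, q(x)
#'       + u_{eddy}(x, y, t) \right]}
#' where `I` is the yearly climate-index value, `r(x)` a coastal taper going
#' to zero at the land edge, `p(x)` a mid-shelf jet profile, `q(x)` an
#' intrusion profile growing offshore, and `s_d` a per-depth-layer shear
#' factor (surface amplified). The eddy term derives from a streamfunction
#' (sum of travelling sinusoidal modes), hence is divergence-free; for a
#' fixed seed it is identical across index values, which makes the
#' domain-mean along-shelf velocity exactly linear (so monotone) in `I`.
#'
#' With the defaults, `gamma > 0` means positive (La Nina) index values
#' drive equatorward (northward, +y) flow and negative (El Nino) values
#' poleward flow, with the sign change at `I = -v0/gamma = 10`, so the
#' predominant flow is poleward except under very strong positive-index
#' (La Nina) conditions; the shoreward intrusion grows with `|I|`. Default
#' speeds keep mean 25-day along-shelf displacements graded over the
#' observed index range (roughly 20-130 km, up to ~250 km once eddy
#' transport is added), several region spacings, so the count and reach of
#' realized connections respond smoothly to the index.
#'
#' @param days length (days) of the hourly velocity window (release window
#'   plus the 25-day pelagic larval duration).
#' @param jet_v0 along-shelf speed (m/s) at index 0 (negative = poleward).
#' @param jet_gamma index sensitivity (m/s per index unit).
#' @param jet_center,jet_width across-shelf position and width (km) of the
#'   jet maximum.
#' @param tide_amp,tide_period tidal along-shelf amplitude (m/s) and period
#'   (hours; default the M2 semidiurnal period).
#' @param intrusion shoreward across-shelf speed per unit `|I|` (m/s).
#' @param eddy_amp eddy velocity scale (m/s); 0 disables the stochastic term.
#' @param n_eddy_modes number of streamfunction modes.
#' @param eddy_wavelength,eddy_period_days ranges (km, days) the modes are
#'   drawn from.
#' @param taper_width width (km) of the coastal taper.
#' @param shear per-layer multipliers for the 1 m, 3 m and 6 m layers.
#' @return list of class `season_config`.
#' @export
season_config <- function(days = 123, jet_v0 = -0.025, jet_gamma = 0.0025,
                          jet_center = 60, jet_width = 35,
                          tide_amp = 0.15, tide_period = 12.42,
                          intrusion = 0.002,
                          eddy_amp = 0.07, n_eddy_modes = 12L,
                          eddy_wavelength = c(40, 150),
                          eddy_period_days = c(5, 20),
                          taper_width = 8, shear = c(1.15, 1, 0.85)) {
  stopifnot(days > 0, tide_period > 0, length(shear) == 3, all(shear > 0),
            eddy_amp >= 0, tide_amp >= 0, intrusion >= 0)
  structure(list(days = days, jet_v0 = jet_v0, jet_gamma = jet_gamma,
                 jet_center = jet_center, jet_width = jet_width,
                 tide_amp = tide_amp, tide_period = tide_period,
                 intrusion = intrusion, eddy_amp = eddy_amp,
                 n_eddy_modes = as.integer(n_eddy_modes),
                 eddy_wavelength = eddy_wavelength,
                 eddy_period_days = eddy_period_days,
                 taper_width = taper_width, shear = shear),
            class = "season_config")
}

#' Generate an hourly climate-index-forced velocity field
#'
#' Produces hourly horizontal currents on the domain grid for one dispersal
#' season, at the three behavioural depth layers (1, 3 and 6 m). See
#' [season_config()] for the flow model. Velocities are exactly zero on
#' land-mask cells and taper to zero at the coast.
#'
#' @param domain a [generate_domain()] object.
#' @param index_value yearly climate-index scalar (SOI units).
#' @param season a [season_config()].
#' @param seed integer seed for the stochastic eddy component (the
#'   deterministic jet/tide/intrusion parts do not consume randomness).
#' @return object of class `velocity_field`: list with `x`, `y` (km), `time`
#'   (hours since window start, hourly), `depths` (m), `u`, `v` (arrays of
#'   dim nx x ny x 3 x nt, m/s), `land_mask`, `index_value`, `seed`.
#' @export
generate_velocity_field <- function(domain, index_value,
                                    season = season_config(), seed = 1L) {
  stopifnot(inherits(domain, "domain"), is.finite(index_value),
            inherits(season, "season_config"))
  gx <- domain$grid$x; gy <- domain$grid$y
  nx <- length(gx); ny <- length(gy)
  time <- seq(0, season$days * 24)          # hours, inclusive end
  nt <- length(time)
  land <- domain$land_mask
  lw <- domain$config$land_width

  ramp <- pmin(1, pmax(0, (gx - lw) / season$taper_width))
  ramp_xy <- matrix(ramp, nx, ny)
  ramp_xy[land] <- 0
  pjet <- 0.7 + 0.6 * exp(-((gx - season$jet_center) / season$jet_width)^2)
  qint <- pmin(1, pmax(0, gx / 60))

  v_det <- (season$jet_v0 + season$jet_gamma * index_value) * pjet  # per x
  u_det <- -season$intrusion * abs(index_value) * qint              # per x

  nxy <- nx * ny
  # eddy field from a streamfunction: u = dpsi/dy, v = -dpsi/dx; each
  # travelling mode contributes a rank-2 (space x time) term via
  # cos(a - b) = cos a cos b + sin a sin b
  if (season$eddy_amp > 0 && season$n_eddy_modes > 0) {
    set.seed(seed)
    K <- season$n_eddy_modes
    lambda <- stats::runif(K, season$eddy_wavelength[1], season$eddy_wavelength[2])
    theta <- stats::runif(K, 0, 2 * pi)
    period_h <- 24 * stats::runif(K, season$eddy_period_days[1],
                                  season$eddy_period_days[2]) *
      sample(c(-1, 1), K, replace = TRUE)
    phase0 <- stats::runif(K, 0, 2 * pi)
    kmag <- 2 * pi / lambda
    kx <- kmag * cos(theta); ky <- kmag * sin(theta)
    # psi amplitude such that |velocity| ~ eddy_amp per mode ensemble
    A <- season$eddy_amp / (kmag * sqrt(K / 2))
    X <- rep(gx, ny); Y <- rep(gy, each = nx)
    PA <- outer(X, kx) * 1 + outer(Y, ky)                   # nxy x K
    PA <- sweep(PA, 2, phase0, "+")
    cosPA <- cos(PA); sinPA <- sin(PA)
    WT <- outer(time, 2 * pi / period_h)                    # nt x K
    cosWT <- cos(WT); sinWT <- sin(WT)
    # d(psi)/dy -> u ; -d(psi)/dx -> v ; mode: A cos(pa - wt)
    u_eddy <- (cosPA %*% diag(A * ky, K)) %*% t(cosWT) +
              (sinPA %*% diag(A * ky, K)) %*% t(sinWT)
    v_eddy <- -((cosPA %*% diag(A * kx, K)) %*% t(cosWT) +
                (sinPA %*% diag(A * kx, K)) %*% t(sinWT))
  } else {
    u_eddy <- v_eddy <- 0
  }

  tide <- season$tide_amp * sin(2 * pi * time / season$tide_period)  # nt

  u_base <- matrix(rep(u_det, ny), nxy, nt) + u_eddy       # nxy x nt
  v_base <- matrix(rep(v_det, ny), nxy, nt) + v_eddy
  v_base <- sweep(v_base, 2, tide, "+")
  rv <- as.vector(ramp_xy)
  u_base <- u_base * rv
  v_base <- v_base * rv

  u <- array(0, c(nx, ny, 3L, nt))
  v <- array(0, c(nx, ny, 3L, nt))
  for (d in 1:3) {
    u[, , d, ] <- season$shear[d] * u_base
    v[, , d, ] <- season$shear[d] * v_base
  }
  structure(list(x = gx, y = gy, time = time, depths = c(1, 3, 6),
                 u = u, v = v, land_mask = land,
                 index_value = index_value, seed = seed, season = season),
            class = "velocity_field")
}

#' Interpolate a velocity field at arbitrary points
#'
#' Bilinear interpolation in (x, y) within a depth layer and linear
#' interpolation in time between hourly snapshots; exact at grid nodes and
#' snapshot times. Because land cells hold zero velocity, interpolated
#' speeds taper to zero approaching the coast.
#'
#' @param field a `velocity_field`.
#' @param x,y query positions (km), vectorized.
#' @param time query time (hours since window start), scalar or vector.
#' @param depth_layer depth in metres; must be one of `field$depths`.
#' @return list with numeric vectors `u` and `v` (m/s). Queries outside the
#'   grid hull or time span are an error.
#' @export
interpolate_velocity <- function(field, x, y, time, depth_layer = 1) {
  stopifnot(inherits(field, "velocity_field"))
  d <- match(depth_layer, field$depths)
  if (is.na(d)) stop("depth_layer must be one of ",
                     paste(field$depths, collapse = ", "), " m")
  n <- max(length(x), length(y), length(time))
  x <- rep_len(x, n); y <- rep_len(y, n); time <- rep_len(time, n)
  gx <- field$x; gy <- field$y; gt <- field$time
  if (any(x < gx[1] | x > gx[length(gx)] | y < gy[1] | y > gy[length(gy)]))
    stop("query position outside the grid hull")
  if (any(time < gt[1] | time > gt[length(gt)]))
    stop("query time outside the field's time span")
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]; dt <- gt[2] - gt[1]
  ix <- pmin(length(gx) - 1L, pmax(1L, findInterval(x, gx)))
  iy <- pmin(length(gy) - 1L, pmax(1L, findInterval(y, gy)))
  it <- pmin(length(gt) - 1L, pmax(1L, findInterval(time, gt)))
  fx <- (x - gx[ix]) / dx; fy <- (y - gy[iy]) / dy; ft <- (time - gt[it]) / dt
  interp1 <- function(arr) {
    val <- function(i, j, k) arr[cbind(i, j, d, k)]
    bil <- function(k)
      (1 - fx) * (1 - fy) * val(ix, iy, k) + fx * (1 - fy) * val(ix + 1L, iy, k) +
      (1 - fx) * fy * val(ix, iy + 1L, k) + fx * fy * val(ix + 1L, iy + 1L, k)
    (1 - ft) * bil(it) + ft * bil(it + 1L)
  }
  list(u = interp1(field$u), v = interp1(field$v))
}

#' Domain-mean along-shelf velocity
#'
#' Mean of the northward component over open-water nodes, all depth layers
#' and the full window; the scalar summary used to characterize a season's
#' net along-shelf transport (positive = equatorward in this Southern-
#' Hemisphere-like domain).
#'
#' @param field a `velocity_field`.
#' @return numeric scalar (m/s).
#' @export
mean_alongshelf_velocity <- function(field) {
  water <- !as.vector(field$land_mask)
  vv <- matrix(field$v, length(field$land_mask))  # nxy x (3*nt)
  mean(vv[water, ])
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("Hourly velocity field: ", length(x$x), "x", length(x$y),
      " grid, ", length(x$time), " hourly steps (",
      round(utils::tail(x$time, 1) / 24), " days), depths ",
      paste(x$depths, collapse = "/"), " m\n", sep = "")
  cat("index value ", x$index_value, "; domain-mean along-shelf v = ",
      signif(mean_alongshelf_velocity(x), 3), " m/s\n", sep = "")
  invisible(x)
}
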