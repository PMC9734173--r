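#' Pelagic survival weight at a given age
#'
#' Deterministic survival under a constant daily mortality rate (default
#' 18\%/day), applied as a continuous exponent: `(1 - m)^age`. A larva
#' surviving the full 25-day pelagic larval duration carries weight
#' `0.82^25 ~ 7.0e-3`.
#'
#' @param age age in days (>= 0; vectorized).
#' @param daily_mortality daily mortality fraction in `[0, 1)`.
#' @return survival weight in `(0, 1]`.
#' @export
pelagic_survival <- function(age, daily_mortality = 0.18) {
  if (any(age < 0)) stop("age must be non-negative")
  stopifnot(daily_mortality >= 0, daily_mortality < 1)
  (1 - daily_mortality)^age
}

#' Stochastic-removal survival simulation
#'
#' The Bernoulli-thinning counterpart of [pelagic_survival()]: each particle
#' independently survives each day with probability `1 - daily_mortality`.
#' The surviving fraction is an unbiased estimator of the deterministic
#' weight `(1 - m)^days`; provided for equivalence checks of the
#' weight-based mortality model.
#'
#' @param n number of particles.
#' @param days integer number of whole days survived.
#' @param daily_mortality daily mortality fraction.
#' @param seed RNG seed.
#' @return list with `survivors`, `fraction`, and the binomial standard
#'   error `se` of the fraction.
#' @export
simulate_survival <- function(n, days = 25, daily_mortality = 0.18,
                              seed = 1L) {
  stopifnot(n >= 1, days >= 0)
  set.seed(seed)
  alive <- rep(TRUE, n)
  for (d in seq_len(days))
    alive[alive] <- stats::runif(sum(alive)) >= daily_mortality
  p <- (1 - daily_mortality)^days
  list(survivors = sum(alive), fraction = sum(alive) / n,
       se = sqrt(p * (1 - p) / n))
}

#' Build sensory zones around reef habitats
#'
#' Each reef polygon is buffered by a fixed radius (default 4 km, the scale
#' of larval-fish sensory capability at the model resolution). Zones are
#' represented exactly: a point lies inside a reef's zone iff its Euclidean
#' distance to the reef rectangle is at most the radius (a rounded-corner
#' rectangle), so membership queries are closed-form rather than polygonal.
#'
#' @param domain a `domain`, or a reef data frame with columns `reef_id`,
#'   `region_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @param radius_km buffer radius in km (> 0).
#' @return object of class `sensory_zones`: list with `reefs` and
#'   `radius_km`.
#' @export
build_sensory_zones <- function(domain, radius_km = 4) {
  stopifnot(radius_km > 0)
  reefs <- if (inherits(domain, "domain")) domain$reefs else domain
  need <- c("reef_id", "region_id", "xmin", "xmax", "ymin", "ymax")
  stopifnot(all(need %in% names(reefs)))
  if (any(reefs$xmin > reefs$xmax | reefs$ymin > reefs$ymax))
    stop("degenerate reef geometry: min edge exceeds max edge")
  reefs <- reefs[order(reefs$reef_id), ]
  structure(list(reefs = reefs, radius_km = radius_km),
            class = "sensory_zones")
}

# distance from points to each reef rectangle; n_points x n_reefs matrix
reef_distances <- function(zones, x, y) {
  r <- zones$reefs
  dx <- pmax(outer(x, r$xmin, function(a, b) b - a), 0) +
        pmax(outer(x, r$xmax, function(a, b) a - b), 0)
  dy <- pmax(outer(y, r$ymin, function(a, b) b - a), 0) +
        pmax(outer(y, r$ymax, function(a, b) a - b), 0)
  sqrt(dx^2 + dy^2)
}

#' Which sensory zone (if any) contains each point
#'
#' Resolves overlapping zones by assigning the reef whose boundary is
#' nearest; exact ties go to the lower `reef_id`.
#'
#' @param zones a `sensory_zones` object.
#' @param x,y point coordinates (km), vectorized.
#' @return integer vector of `reef_id` (NA where outside all zones).
#' @export
zone_contains <- function(zones, x, y) {
  stopifnot(inherits(zones, "sensory_zones"))
  d <- reef_distances(zones, x, y)
  inside <- d <= zones$radius_km
  idx <- apply(d, 1, which.min)              # first minimum = lower reef_id
  hit <- inside[cbind(seq_along(x), idx)]
  out <- zones$reefs$reef_id[idx]
  out[!hit] <- NA_integer_
  out
}

#' Areas of the sensory zones
#'
#' Closed form for a rectangle of width w and height h buffered by radius r:
#' `w h + 2 (w + h) r + pi r^2`. A point-like reef gives `pi r^2` (~50.27
#' km^2 at the default 4 km radius).
#'
#' @param zones a `sensory_zones` object.
#' @return numeric vector of zone areas (km^2), one per reef.
#' @export
zone_area <- function(zones) {
  stopifnot(inherits(zones, "sensory_zones"))
  w <- zones$reefs$xmax - zones$reefs$xmin
  h <- zones$reefs$ymax - zones$reefs$ymin
  r <- zones$radius_km
  w * h + 2 * (w + h) * r + pi * r^2
}

#' Evaluate settlement along a recorded trajectory
#'
#' Applies the settlement rule to one recorded trajectory: the first state
#' (at age >= `competency_start`) whose position lies within any sensory
#' zone settles the larva to that reef's region, with weight
#' `pelagic_survival(age) * (1 - settlement_mortality)` (survival taken at
#' contact age). A larva that never contacts a zone within the pelagic
#' larval duration is excluded (returns `NULL`), as are lost particles.
#'
#' @param trajectory a matrix with columns (time_hours, x, y) starting at
#'   release (as stored by `track_particles(..., record = TRUE)`), or a list
#'   with elements `path` (that matrix) and `status`.
#' @param zones a `sensory_zones` object.
#' @param competency_start age (days) from which settlement is possible, in
#'   `[0, 25]`.
#' @param settlement_mortality mortality fraction applied while attempting
#'   to settle (default 0.13).
#' @param daily_mortality pelagic daily mortality (default 0.18).
#' @param source_region optional source region id carried into the record.
#' @return a one-row data frame (`source_region`, `settle_reef`,
#'   `settle_region`, `age_days`, `weight`) or `NULL` if the larva never
#'   settles.
#' @export
evaluate_settlement <- function(trajectory, zones, competency_start = 0,
                                settlement_mortality = 0.13,
                                daily_mortality = 0.18,
                                source_region = NA_integer_) {
  stopifnot(competency_start >= 0, competency_start <= 25,
            settlement_mortality >= 0, settlement_mortality < 1)
  status <- "pelagic"
  if (is.list(trajectory) && !is.null(trajectory$path)) {
    status <- trajectory$status %||% "pelagic"
    trajectory <- trajectory$path
  }
  if (identical(status, "lost") || is.null(trajectory) ||
      nrow(trajectory) == 0) return(NULL)
  age_days <- (trajectory[, 1] - trajectory[1, 1]) / 24
  eligible <- which(age_days >= competency_start)
  if (!length(eligible)) return(NULL)
  reef <- zone_contains(zones, trajectory[eligible, 2], trajectory[eligible, 3])
  k <- which(!is.na(reef))[1]
  if (is.na(k)) return(NULL)
  i <- eligible[k]
  rid <- reef[k]
  age <- age_days[i]
  data.frame(source_region = source_region,
             settle_reef = rid,
             settle_region = zones$reefs$region_id[match(rid, zones$reefs$reef_id)],
             age_days = age,
             weight = pelagic_survival(age, daily_mortality) *
               (1 - settlement_mortality))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Settlement records from a tracked particle set
#'
#' Converts the settled particles of a [track_particles()] result into a
#' settlement-record table, attaching the mortality-derived weight
#' `pelagic_survival(age) * (1 - settlement_mortality)`.
#'
#' @param tracks a `trajectory_set`.
#' @param settlement_mortality settlement-stage mortality fraction.
#' @param daily_mortality pelagic daily mortality fraction.
#' @return data frame of class `settlement_records` with columns
#'   `particle_id`, `source_region`, `settle_region`, `age_days`, `weight`.
#' @export
settlement_records <- function(tracks, settlement_mortality = 0.13,
                               daily_mortality = 0.18) {
  stopifnot(inherits(tracks, "trajectory_set"))
  s <- tracks[tracks$status == "settled", , drop = FALSE]
  out <- data.frame(particle_id = s$particle_id,
                    source_region = s$region_id,
                    settle_region = s$settle_region,
                    age_days = s$settle_age_days,
                    weight = pelagic_survival(s$settle_age_days,
                                              daily_mortality) *
                      (1 - settlement_mortality))
  structure(out, class = c("settlement_records", "data.frame"))
}
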