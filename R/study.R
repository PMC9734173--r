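#' Study configuration
#'
#' Assembles every tunable of the end-to-end study into one serializable
#' list. The defaults reproduce the study conditions: 8 dispersal years
#' forced by the packaged 2010-2017 monthly SOI, 29 regions / 141 seed
#' cells, releases October-December (92 daily releases), a 25-day pelagic
#' larval duration, 18\%/day pelagic mortality, 13\% settlement mortality
#' and 4 km sensory zones. `rate` defaults to the full 100 particles per
#' cell per day; desk-scale runs reduce it (connectivity is a per-release
#' probability, so the expected matrices are rate-invariant).
#'
#' @param domain a [domain_config()].
#' @param index_source `"table1"` or `"simulated"` (see
#'   [load_or_generate_index()]).
#' @param season a [season_config()].
#' @param rate particles per cell per day.
#' @param release_days number of daily releases.
#' @param dt tracking step (hours).
#' @param diffusion horizontal diffusivity (km^2/h).
#' @param pld pelagic larval duration (days).
#' @param daily_mortality,settlement_mortality mortality parameters.
#' @param zone_radius_km sensory-zone radius (km).
#' @param competency_start age (days) from which larvae can settle; the
#'   study default (20) makes larvae competent once they descend to the
#'   6 m layer, so settlement happens near the end of the PLD.
#' @param source_sectors,excluded_southernmost directional-analysis
#'   source filter: sectors counted as sources, and how many southernmost
#'   regions to exclude.
#' @param seed master seed; per-year substreams are derived from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(domain = domain_config(),
                         index_source = "table1",
                         season = season_config(),
                         rate = 100, release_days = 92,
                         dt = 0.5, diffusion = 0, pld = 25,
                         daily_mortality = 0.18,
                         settlement_mortality = 0.13,
                         zone_radius_km = 4, competency_start = 20,
                         source_sectors = c("central", "southern"),
                         excluded_southernmost = 2L,
                         seed = 1L) {
  structure(list(domain = domain, index_source = index_source,
                 season = season, rate = rate, release_days = release_days,
                 dt = dt, diffusion = diffusion, pld = pld,
                 daily_mortality = daily_mortality,
                 settlement_mortality = settlement_mortality,
                 zone_radius_km = zone_radius_km,
                 competency_start = competency_start,
                 source_sectors = source_sectors,
                 excluded_southernmost = as.integer(excluded_southernmost),
                 seed = as.integer(seed)),
            class = "study_config")
}

# per-year RNG substream derived from the master seed (kept below 2^31)
year_seed <- function(master, year_index) {
  (as.integer(master) * 1009L + 101L * as.integer(year_index)) %% 2147483647L
}

#' Run the full multi-year connectivity study
#'
#' For each dispersal year: generate the climate-index-forced velocity
#' field from that year's index mean, release particles on the schedule,
#' track them with RK4 and the depth-by-age behaviour, settle them against
#' the sensory zones, and build the annual connectivity matrix. Then derive
#' the stack statistics (mean, CV, anomalies), the per-year directional
#' summaries, the directional-vs-index regressions (linear for poleward and
#' equatorward, quadratic for across-shelf), the mean-vs-CV exponential
#' decay fit and the mean-vs-CV Spearman rank correlation. Deterministic
#' for a fixed seed.
#'
#' @param config a [study_config()].
#' @param seed master seed (overrides `config$seed`).
#' @param outdir optional directory; when given, all artifacts plus the
#'   exact config and seed are written there via [write_study()].
#' @param years optional subset of dispersal years to run.
#' @param verbose print per-year progress (particle counts, timing).
#' @return object of class `connectivity_study`: list with `config`,
#'   `seed`, `domain`, `index` (climate series), `index_means`, `stack`,
#'   `mean_matrix`, `cv_matrix`, `anomalies`, `directional` (per-year data
#'   frame), `regressions` (poleward, equatorward, across_shelf,
#'   mean_vs_cv), `mean_cv_spearman`, `counts`, `log`.
#' @export
run_study <- function(config = study_config(), seed = config$seed,
                      outdir = NULL, years = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  t_start <- Sys.time()
  logline <- character()
  say <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    if (verbose) message(msg)
  }
  say("study seed %d", as.integer(seed))
  domain <- generate_domain(config$domain, seed = seed)
  index <- load_or_generate_index(config$index_source, seed = seed)
  if (!is.null(years)) {
    keep <- match(years, index$years)
    if (anyNA(keep)) stop("requested year absent from the index series")
    index$years <- index$years[keep]
    index$monthly <- index$monthly[keep, , drop = FALSE]
    index$event <- index$event[keep]
  }
  imeans <- yearly_mean_index(index)
  zones <- build_sensory_zones(domain, config$zone_radius_km)
  schedule <- make_release_schedule(domain, rate = config$rate,
                                    n_days = config$release_days)
  matrices <- vector("list", length(index$years))
  counts <- data.frame(year = index$years, released = NA_real_,
                       settled = NA_real_, pelagic = NA_real_,
                       lost = NA_real_)
  for (k in seq_along(index$years)) {
    yr <- index$years[k]
    ys <- year_seed(seed, k)
    t0 <- Sys.time()
    field <- generate_velocity_field(domain, imeans[k],
                                     season = config$season, seed = ys)
    tracks <- track_particles(schedule, field, dt = config$dt,
                              diffusion = config$diffusion, seed = ys,
                              zones = zones,
                              competency_start = config$competency_start,
                              pld = config$pld)
    rm(field)
    settle <- settlement_records(tracks,
                                 settlement_mortality = config$settlement_mortality,
                                 daily_mortality = config$daily_mortality)
    matrices[[k]] <- build_connectivity_matrix(settle, schedule, domain,
                                               year = yr)
    counts[k, 2:5] <- c(nrow(tracks), sum(tracks$status == "settled"),
                        sum(tracks$status == "pelagic"),
                        sum(tracks$status == "lost"))
    say("year %s (index %.2f): released %d, settled %d, pelagic %d, lost %d (%.1f s)",
        yr, imeans[k], counts$released[k], counts$settled[k],
        counts$pelagic[k], counts$lost[k],
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    rm(tracks); gc(FALSE)
  }
  stack <- connectivity_stack(matrices, years = index$years)
  mean_matrix <- mean_connectivity(stack)
  multi_year <- length(index$years) >= 2
  if (!multi_year)
    say("single-year run: CV, anomaly and regression stages skipped")
  cv_matrix <- if (multi_year) cv_connectivity(stack) else NULL
  anomalies <- if (multi_year) anomaly_matrices(stack) else NULL
  excl <- southernmost_regions(domain, config$excluded_southernmost)
  directional <- do.call(rbind, lapply(seq_along(matrices), function(k)
    cbind(year = index$years[k], index_mean = imeans[k],
          directional_summary(matrices[[k]], domain,
                              source_sectors = config$source_sectors,
                              excluded_regions = excl))))
  regressions <- list(poleward = NULL, equatorward = NULL,
                      across_shelf = NULL, mean_vs_cv = NULL)
  mean_cv_spearman <- NULL
  if (multi_year && length(index$years) >= 4) {
    regressions$poleward <- regress_on_index(directional$mean_poleward,
                                             imeans, "linear")
    regressions$equatorward <- regress_on_index(directional$mean_equatorward,
                                                imeans, "linear")
    regressions$across_shelf <- regress_on_index(directional$mean_across_shelf,
                                                 imeans, "quadratic")
  }
  if (multi_year) {
    mm <- as.vector(unclass(mean_matrix)); cc <- as.vector(unclass(cv_matrix))
    ok <- is.finite(mm) & is.finite(cc) & mm > 0
    if (sum(ok) >= 3) {
      regressions$mean_vs_cv <- fit_mean_vs_cv_decay(mm[ok], cc[ok])
      mean_cv_spearman <- if (stats::sd(mm[ok]) > 0 && stats::sd(cc[ok]) > 0)
        stats::cor(mm[ok], cc[ok], method = "spearman") else NA_real_
    }
  }
  say("total %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  study <- structure(list(config = config, seed = as.integer(seed),
                          domain = domain, index = index,
                          index_means = imeans, stack = stack,
                          mean_matrix = mean_matrix, cv_matrix = cv_matrix,
                          anomalies = anomalies, directional = directional,
                          regressions = regressions,
                          mean_cv_spearman = mean_cv_spearman,
                          counts = counts, log = logline),
                     class = "connectivity_study")
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' @export
print.connectivity_study <- function(x, ...) {
  cat("Larval connectivity study: ", length(x$stack$years), " years (",
      paste(range(x$stack$years), collapse = "-"), "), ",
      nrow(x$domain$regions), " regions, seed ", x$seed, "\n", sep = "")
  cat("particles released per year: ", x$counts$released[1], "\n", sep = "")
  if (!is.null(x$regressions$poleward)) {
    cat("poleward connectivity vs index:    slope ",
        signif(x$regressions$poleward$coefficients["x"], 3), ", r^2 ",
        signif(x$regressions$poleward$r_squared, 2), "\n", sep = "")
    cat("equatorward connectivity vs index: slope ",
        signif(x$regressions$equatorward$coefficients["x"], 3), ", r^2 ",
        signif(x$regressions$equatorward$r_squared, 2), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.connectivity_study <- function(object, ...) {
  x <- object
  cv <- if (!is.null(x$cv_matrix)) {
    v <- x$cv_matrix[is.finite(x$cv_matrix)]
    c(min = min(v), median = stats::median(v), max = max(v))
  }
  out <- list(years = x$stack$years, index_means = x$index_means,
              counts = x$counts, directional = x$directional,
              regressions = x$regressions, cv_range = cv,
              mean_cv_spearman = x$mean_cv_spearman)
  class(out) <- "summary.connectivity_study"
  out
}

#' @export
print.summary.connectivity_study <- function(x, ...) {
  cat("Per-year directional connectivity (sources: central/southern",
      "minus southernmost exclusions):\n")
  print(x$directional, digits = 3, row.names = FALSE)
  if (!is.null(x$regressions$poleward)) {
    cat("\nRegressions on the yearly index mean:\n")
    for (nm in c("poleward", "equatorward", "across_shelf")) {
      r <- x$regressions[[nm]]
      cat(sprintf("  %-13s %-10s r^2 = %.2f, p = %.3g\n", nm, r$form,
                  r$r_squared, r$p_value))
    }
  }
  if (!is.null(x$regressions$mean_vs_cv))
    cat(sprintf("  mean vs CV    exp decay  r^2 = %.2f (Spearman rho = %.2f)\n",
                x$regressions$mean_vs_cv$r_squared, x$mean_cv_spearman))
  if (!is.null(x$cv_range))
    cat(sprintf("CV of realized connections: %.2f-%.2f, median %.2f\n",
                x$cv_range["min"], x$cv_range["max"], x$cv_range["median"]))
  invisible(x)
}

#' Overview plot of a connectivity study
#'
#' Four panels: the mean connectivity matrix, the CV matrix, and the
#' poleward / equatorward directional means against the yearly index with
#' their fitted lines.
#'
#' @param x a `connectivity_study`.
#' @param ... unused.
#' @export
plot.connectivity_study <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$mean_matrix, main = "mean connectivity")
  if (!is.null(x$cv_matrix)) plot(x$cv_matrix, main = "CV")
  d <- x$directional
  for (nm in c("mean_poleward", "mean_equatorward")) {
    graphics::plot(d$index_mean, d[[nm]], pch = 19,
                   xlab = "yearly index mean", ylab = nm)
    r <- x$regressions[[sub("mean_", "", nm)]]
    if (!is.null(r)) graphics::abline(r$fit, lty = 2)
  }
  invisible(x)
}
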