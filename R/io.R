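#' Write and read a domain as GeoJSON plus a descriptor
#'
#' The reef polygons go to a GeoJSON FeatureCollection (one Polygon feature
#' per reef with properties `reef_id`, `region_id`, `region_name`, `band`,
#' `sector`, `latitude_rank`); the grid, land mask and region table go to a
#' JSON descriptor written alongside (`<path>.descriptor.json`). Real
#' geometry in the same schema can be supplied in place of the generated
#' one.
#'
#' @param domain a `domain`.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_domain_geojson <- function(domain, path) {
  stopifnot(inherits(domain, "domain"))
  reg <- domain$regions
  feats <- lapply(seq_len(nrow(domain$reefs)), function(k) {
    r <- domain$reefs[k, ]
    g <- reg[match(r$region_id, reg$region_id), ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = list(reef_id = r$reef_id, region_id = r$region_id,
                           region_name = g$name, band = g$band,
                           sector = g$sector,
                           latitude_rank = g$latitude_rank),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  desc <- list(grid = domain$grid,
               land_mask = list(dim = dim(domain$land_mask),
                                land = which(domain$land_mask)),
               regions = domain$regions,
               seed_cells = domain$seed_cells,
               config = unclass(domain$config))
  jsonlite::write_json(desc, paste0(path, ".descriptor.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain_geojson
#' @export
read_domain_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  reefs <- do.call(rbind, lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(reef_id = f$properties$reef_id,
               region_id = f$properties$region_id,
               xmin = min(xs), xmax = max(xs),
               ymin = min(ys), ymax = max(ys))
  }))
  dpath <- paste0(path, ".descriptor.json")
  if (!file.exists(dpath)) stop("missing domain descriptor: ", dpath)
  desc <- jsonlite::read_json(dpath, simplifyVector = TRUE)
  land <- matrix(FALSE, desc$land_mask$dim[1], desc$land_mask$dim[2])
  land[desc$land_mask$land] <- TRUE
  cfg <- desc$config; class(cfg) <- "domain_config"
  structure(list(grid = list(x = desc$grid$x, y = desc$grid$y,
                             dx = desc$grid$dx, dy = desc$grid$dy),
                 land_mask = land, regions = desc$regions,
                 reefs = reefs[order(reefs$reef_id), ],
                 seed_cells = desc$seed_cells, config = cfg),
            class = "domain")
}

#' Write and read a velocity field as plain text
#'
#' Long-format CSV with columns `time`, `depth`, `y`, `x`, `u`, `v` (one row
#' per node-layer-hour), plus a JSON metadata sidecar
#' (`<path>.meta.json`) carrying the land mask, index value and seed.
#' Intended for small fields (exchange and round-trip checks); full-season
#' fields are kept in memory.
#'
#' @param field a `velocity_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$u)
  grid <- expand.grid(x = field$x, y = field$y, depth = field$depths,
                      time = field$time)
  df <- data.frame(time = grid$time, depth = grid$depth, y = grid$y,
                   x = grid$x, u = as.vector(field$u), v = as.vector(field$v))
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(dim = d, x = field$x, y = field$y, time = field$time,
               depths = field$depths,
               land = which(field$land_mask),
               land_dim = dim(field$land_mask),
               index_value = field$index_value, seed = field$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  mpath <- paste0(path, ".meta.json")
  if (!file.exists(mpath)) stop("missing velocity metadata: ", mpath)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("time", "depth", "y", "x", "u", "v")
  if (!all(need %in% names(df)))
    stop("velocity file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  d <- meta$dim
  if (nrow(df) != prod(d)) stop("velocity file size does not match dims")
  # rows were written in column-major (x fastest) order
  land <- matrix(FALSE, meta$land_dim[1], meta$land_dim[2])
  land[meta$land] <- TRUE
  structure(list(x = meta$x, y = meta$y, time = meta$time,
                 depths = meta$depths,
                 u = array(df$u, d), v = array(df$v, d),
                 land_mask = land, index_value = meta$index_value,
                 seed = meta$seed, season = NULL),
            class = "velocity_field")
}

#' Write and read a connectivity matrix as CSV
#'
#' Rows are sources and columns sinks, both in north-to-south region order;
#' the first column holds the source region names. Values round-trip at full
#' double precision.
#'
#' @param matrix a `connectivity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  df <- data.frame(region = rownames(matrix),
                   format(as.data.frame(unclass(matrix)), digits = 17,
                          scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @param year year label to attach on read.
#' @export
read_connectivity_csv <- function(path, year = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "region")
    stop("connectivity CSV ", path, " lacks a leading 'region' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- apply(m, c(1, 2), as.numeric)
  dimnames(m) <- list(source = df$region, sink = colnames(df)[-1])
  structure(m, year = year, class = c("connectivity_matrix", "matrix"))
}

#' Write the artifacts of a completed study
#'
#' Persists, under `dir`: the run's configuration and seed
#' (`config.json`), the annual/mean/CV matrices and anomaly-sign matrices
#' (CSV), the per-year directional summaries (`directional_summary.csv`),
#' regression results (`regressions.json`) and a plain-text run log —
#' everything needed to regenerate or audit the run.
#'
#' @param study a `connectivity_study` from [run_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "connectivity_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  jsonlite::write_json(list(config = unclass_deep(cfg), seed = study$seed),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  for (i in seq_along(study$stack$matrices))
    write_connectivity_csv(study$stack$matrices[[i]],
                           file.path(dir, sprintf("connectivity_%s.csv",
                                                  study$stack$years[i])))
  write_connectivity_csv(study$mean_matrix, file.path(dir, "connectivity_mean.csv"))
  if (!is.null(study$cv_matrix))
    write_connectivity_csv(study$cv_matrix, file.path(dir, "connectivity_cv.csv"))
  if (!is.null(study$anomalies))
    for (y in names(study$anomalies$signs))
      utils::write.csv(study$anomalies$signs[[y]],
                       file.path(dir, sprintf("anomaly_sign_%s.csv", y)))
  utils::write.csv(study$directional, file.path(dir, "directional_summary.csv"),
                   row.names = FALSE)
  regs <- lapply(study$regressions, function(r) {
    if (is.null(r)) return(NULL)
    if (inherits(r, "index_regression"))
      list(form = r$form, coefficients = as.list(r$coefficients),
           r_squared = r$r_squared, p_value = r$p_value, n = r$n)
    else list(a = r$a, b = r$b, r_squared = r$r_squared,
              p_value = r$p_value, n = r$n)
  })
  jsonlite::write_json(regs, file.path(dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(study$log, file.path(dir, "run.log"))
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
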