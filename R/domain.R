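#' Domain configuration for the idealized shelf sea
#'
#' Builds the parameter list consumed by [generate_domain()]. Coordinates are
#' local Cartesian kilometres on a regular grid; `y` increases northward and
#' the study area is Southern-Hemisphere-like, so "poleward" means decreasing
#' `y`. The coast runs along the western edge (low `x`); reef regions sit in
#' an inshore and an offshore (mid- to outer-shelf) band.
#'
#' The default configuration mirrors the scale of the study system: 29
#' regions in 3 latitudinal sectors (northern, central, southern), alternating
#' inshore/offshore bands, and 141 reefs (one seed cell each).
#'
#' @param extent_x,extent_y domain extent (km) across- and along-shelf.
#' @param dx,dy grid spacing (km) of the velocity grid.
#' @param land_width width (km) of the coastal land strip at low `x`.
#' @param sectors character vector of sector names, north to south.
#' @param regions_per_sector integer vector, one entry per sector.
#' @param reefs_per_region integer vector of length `sum(regions_per_sector)`
#'   (recycled if shorter); default gives 141 reefs over 29 regions.
#' @param inshore_x,offshore_x numeric length-2 across-shelf extents (km) of
#'   the two reef bands.
#' @param region_height along-shelf height (km) of a region's reef cluster.
#' @param reef_size side length (km) of a (square) reef polygon; also the
#'   seed-cell size.
#' @param y_margin along-shelf margin (km) kept free at both domain ends.
#' @return a list of class `domain_config`.
#' @export
domain_config <- function(extent_x = 96, extent_y = 600, dx = 8, dy = 8,
                          land_width = 8,
                          sectors = c("northern", "central", "southern"),
                          regions_per_sector = c(9L, 10L, 10L),
                          reefs_per_region = NULL,
                          inshore_x = c(12, 28), offshore_x = c(48, 88),
                          region_height = 16, reef_size = 4,
                          y_margin = 20) {
  stopifnot(length(sectors) == length(regions_per_sector),
            all(regions_per_sector >= 1),
            extent_x > land_width, extent_y > 2 * y_margin,
            dx > 0, dy > 0, reef_size > 0)
  n_regions <- sum(regions_per_sector)
  if (is.null(reefs_per_region)) {
    # 25 regions x 5 reefs + 4 regions x 4 reefs = 141 at the default scale
    reefs_per_region <- rep(5L, n_regions)
    if (n_regions >= 4) reefs_per_region[seq(n_regions - 3, n_regions)] <- 4L
  }
  reefs_per_region <- rep_len(as.integer(reefs_per_region), n_regions)
  structure(list(extent_x = extent_x, extent_y = extent_y, dx = dx, dy = dy,
                 land_width = land_width, sectors = sectors,
                 regions_per_sector = as.integer(regions_per_sector),
                 reefs_per_region = reefs_per_region,
                 inshore_x = inshore_x, offshore_x = offshore_x,
                 region_height = region_height, reef_size = reef_size,
                 y_margin = y_margin),
            class = "domain_config")
}

# deterministic low-discrepancy sequence used for reef/particle placement,
# so that zero-noise runs are independent of the RNG seed
van_der_corput <- function(n, base = 2L) {
  vapply(seq_len(n), function(i) {
    v <- 0; f <- 1 / base
    while (i > 0) { v <- v + f * (i %% base); i <- i %/% base; f <- f / base }
    v
  }, numeric(1))
}

#' Generate the idealized shelf domain
#'
#' Lays out latitude-ordered reef regions on the shelf: region ranks run 1
#' (northernmost) to R (southernmost) with no ties, bands alternate inshore/
#' offshore with latitude, and each region holds a cluster of square reef
#' polygons, each carrying one seed cell. Reef placement within a region uses
#' a deterministic slot grid plus a small seeded jitter.
#'
#' @param config a [domain_config()] list.
#' @param seed integer; controls only the within-slot jitter of reef
#'   placement.
#' @return an object of class `domain`: list with `grid` (x/y node vectors
#'   and spacings), `land_mask` (nx x ny logical, TRUE = land), `regions`
#'   (data frame: region_id, name, sector, band, latitude_rank, n_reefs),
#'   `reefs` (data frame: reef_id, region_id, xmin, xmax, ymin, ymax) and
#'   `seed_cells` (data frame: cell_id, reef_id, region_id, x, y, half).
#' @examples
#' dom <- generate_domain(domain_config(), seed = 1)
#' nrow(dom$regions)     # 29
#' nrow(dom$seed_cells)  # 141
#' @export
generate_domain <- function(config = domain_config(), seed = 1L) {
  stopifnot(inherits(config, "domain_config"))
  set.seed(seed)
  gx <- seq(0, config$extent_x, by = config$dx)
  gy <- seq(0, config$extent_y, by = config$dy)
  land <- matrix(gx < config$land_width, nrow = length(gx), ncol = length(gy))

  n_regions <- sum(config$regions_per_sector)
  sector <- rep(config$sectors, config$regions_per_sector)
  rank <- seq_len(n_regions)
  band <- ifelse(rank %% 2L == 1L, "inshore", "offshore")
  # region centres, equally spaced from north (high y) to south (low y)
  y_top <- config$extent_y - config$y_margin
  y_bot <- config$y_margin
  yc <- if (n_regions == 1) mean(c(y_top, y_bot)) else
    seq(y_top, y_bot, length.out = n_regions)
  regions <- data.frame(region_id = rank,
                        name = sprintf("%s-%s-%02d", substr(sector, 1, 1),
                                       ifelse(band == "inshore", "in", "off"),
                                       rank),
                        sector = sector, band = band, latitude_rank = rank,
                        n_reefs = config$reefs_per_region,
                        y_center = yc, stringsAsFactors = FALSE)

  rs <- config$reef_size
  reefs <- vector("list", n_regions)
  next_id <- 1L
  for (r in seq_len(n_regions)) {
    n <- config$reefs_per_region[r]
    xr <- if (band[r] == "inshore") config$inshore_x else config$offshore_x
    # slot grid: enough non-overlapping slots for n reefs
    ncol_s <- max(1L, floor((xr[2] - xr[1]) / (1.5 * rs)))
    nrow_s <- ceiling(n / ncol_s)
    if (nrow_s * rs > config$region_height)
      stop("region ", r, ": reefs do not fit in the region box; ",
           "reduce reefs_per_region or reef_size")
    sx <- xr[1] + (seq_len(ncol_s) - 0.5) * (xr[2] - xr[1]) / ncol_s
    sy <- yc[r] + (seq_len(nrow_s) - (nrow_s + 1) / 2) * rs
    slots <- expand.grid(x = sx, y = sy)[seq_len(n), ]
    # jitter keeps the reef inside its slot (slots are >= rs wide)
    jx <- (stats::runif(n) - 0.5) * pmax(0, (xr[2] - xr[1]) / ncol_s - rs)
    reefs[[r]] <- data.frame(reef_id = seq.int(next_id, length.out = n),
                             region_id = r,
                             xmin = slots$x + jx - rs / 2,
                             xmax = slots$x + jx + rs / 2,
                             ymin = slots$y - rs / 2,
                             ymax = slots$y + rs / 2)
    next_id <- next_id + n
  }
  reefs <- do.call(rbind, reefs)
  seed_cells <- data.frame(cell_id = reefs$reef_id, reef_id = reefs$reef_id,
                           region_id = reefs$region_id,
                           x = (reefs$xmin + reefs$xmax) / 2,
                           y = (reefs$ymin + reefs$ymax) / 2,
                           half = rs / 2)
  dom <- structure(list(grid = list(x = gx, y = gy, dx = config$dx,
                                    dy = config$dy),
                        land_mask = land, regions = regions, reefs = reefs,
                        seed_cells = seed_cells, config = config),
                   class = "domain")
  report <- validate_domain(dom)
  if (length(report)) stop("invalid domain:\n  ", paste(report, collapse = "\n  "))
  dom
}

#' Validate a domain against its structural invariants
#'
#' Checks: strict north-to-south latitude ordering with no ties; each reef in
#' exactly one region; each seed cell overlapping exactly one reef; no reef
#' intersecting the land strip or leaving the domain; no pair of reef
#' polygons overlapping.
#'
#' @param dom a `domain`.
#' @return character vector of violation messages (empty if valid).
#' @export
validate_domain <- function(dom) {
  stopifnot(inherits(dom, "domain"))
  bad <- character()
  rk <- dom$regions$latitude_rank
  if (anyDuplicated(rk) || any(diff(order(rk)) <= 0))
    bad <- c(bad, "latitude_rank has ties or is not a strict ordering")
  if (!all(order(-dom$regions$y_center) == order(rk)))
    bad <- c(bad, "latitude_rank does not order regions north to south")
  if (!all(dom$reefs$region_id %in% dom$regions$region_id))
    bad <- c(bad, "reef assigned to unknown region")
  if (any(dom$reefs$xmin < dom$config$land_width))
    bad <- c(bad, "reef polygon intersects the land mask")
  if (any(dom$reefs$xmax > dom$config$extent_x |
          dom$reefs$ymin < 0 | dom$reefs$ymax > dom$config$extent_y))
    bad <- c(bad, "reef polygon outside the domain")
  # pairwise reef overlap (strict interior overlap)
  n <- nrow(dom$reefs)
  if (n > 1) {
    r <- dom$reefs
    for (i in seq_len(n - 1)) {
      j <- seq(i + 1, n)
      ov <- r$xmin[j] < r$xmax[i] & r$xmax[j] > r$xmin[i] &
            r$ymin[j] < r$ymax[i] & r$ymax[j] > r$ymin[i]
      if (any(ov)) { bad <- c(bad, "overlapping reef polygons"); break }
    }
  }
  # each seed cell overlaps exactly its own reef
  sc <- dom$seed_cells
  for (k in seq_len(nrow(sc))) {
    hits <- which(sc$x[k] + sc$half[k] > dom$reefs$xmin &
                  sc$x[k] - sc$half[k] < dom$reefs$xmax &
                  sc$y[k] + sc$half[k] > dom$reefs$ymin &
                  sc$y[k] - sc$half[k] < dom$reefs$ymax)
    if (!identical(hits, which(dom$reefs$reef_id == sc$reef_id[k]))) {
      bad <- c(bad, "seed cell overlapping zero or multiple reefs")
      break
    }
  }
  bad
}

#' @export
print.domain <- function(x, ...) {
  cat("Idealized shelf domain: ",
      diff(range(x$grid$x)), " x ", diff(range(x$grid$y)), " km, ",
      length(x$grid$x), "x", length(x$grid$y), " grid nodes (",
      x$grid$dx, " km spacing)\n", sep = "")
  cat(nrow(x$regions), " regions (",
      paste(sprintf("%s: %d", unique(x$regions$sector),
                    table(factor(x$regions$sector,
                                 levels = unique(x$regions$sector)))),
            collapse = ", "),
      "), bands: ", sum(x$regions$band == "inshore"), " inshore / ",
      sum(x$regions$band == "offshore"), " offshore\n", sep = "")
  cat(nrow(x$reefs), " reefs / seed cells\n", sep = "")
  invisible(x)
}

#' @export
plot.domain <- function(x, ...) {
  graphics::plot(NA, xlim = range(x$grid$x), ylim = range(x$grid$y),
                 xlab = "across-shelf x (km)", ylab = "along-shelf y (km)",
                 asp = 1, ...)
  graphics::rect(0, 0, x$config$land_width, max(x$grid$y),
                 col = "grey80", border = NA)
  cols <- grDevices::hcl.colors(nrow(x$regions), "Zissou 1")
  with(x$reefs, graphics::rect(xmin, ymin, xmax, ymax,
                               col = cols[region_id], border = NA))
  invisible(x)
}
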