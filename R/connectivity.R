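#' Build an annual region-by-region connectivity matrix
#'
#' `C[i, j]` is the probability that a larva spawned in region `i` settles
#' in region `j`: the sum of settled weights from `i` to `j` divided by the
#' total number of particles released from `i` (the default denominator —
#' mortality therefore depresses probabilities; `denominator = "settlers"`
#' conditions on settlement instead). The diagonal is larval retention.
#' Regions are ordered north to south by `latitude_rank`. Rows of regions
#' with zero releases are `NA` (masked).
#'
#' @param settlements a [settlement_records()] data frame (or any data frame
#'   with `source_region`, `settle_region`, `weight`).
#' @param schedule the [make_release_schedule()] the settlements came from.
#' @param domain the `domain`.
#' @param year optional year label.
#' @param denominator `"released"` (default) or `"settlers"`.
#' @return object of class `connectivity_matrix`: an R x R numeric matrix
#'   with region names as dimnames and attributes `year`, `regions`,
#'   `releases`.
#' @export
build_connectivity_matrix <- function(settlements, schedule, domain,
                                      year = NA,
                                      denominator = c("released", "settlers")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(domain, "domain"))
  reg <- domain$regions[order(domain$regions$latitude_rank), ]
  R <- nrow(reg)
  ids <- reg$region_id
  if (nrow(settlements) > 0 &&
      (!all(settlements$source_region %in% ids) ||
       !all(settlements$settle_region %in% ids)))
    stop("settlement references a region unknown to the domain")
  releases <- vapply(ids, function(i)
    sum(schedule$count[schedule$region_id == i]), numeric(1))
  W <- matrix(0, R, R, dimnames = list(source = reg$name, sink = reg$name))
  if (nrow(settlements) > 0) {
    si <- match(settlements$source_region, ids)
    sj <- match(settlements$settle_region, ids)
    for (k in seq_len(nrow(settlements)))
      W[si[k], sj[k]] <- W[si[k], sj[k]] + settlements$weight[k]
  }
  denom <- if (denominator == "released") releases else rowSums(W)
  C <- W / ifelse(denom > 0, denom, NA)
  if (denominator == "settlers") C[rowSums(W) == 0, ] <- 0
  structure(C, year = year, regions = reg, releases = releases,
            settled_weight = sum(W), class = c("connectivity_matrix", "matrix"))
}

#' Stack annual connectivity matrices
#'
#' Collects the annual matrices of a multi-year study (default scale: eight
#' years) into a single object from which the temporal statistics — mean,
#' coefficient of variation, anomalies — are derived.
#'
#' @param matrices list of `connectivity_matrix` objects sharing region
#'   ordering and dimension.
#' @param years vector of year labels (defaults to the matrices' `year`
#'   attributes).
#' @return object of class `connectivity_stack`.
#' @export
connectivity_stack <- function(matrices, years = NULL) {
  stopifnot(length(matrices) >= 1)
  dims <- vapply(matrices, function(m) dim(m)[1], numeric(1))
  if (length(unique(dims)) != 1)
    stop("all matrices must share dimension")
  nm <- dimnames(matrices[[1]])
  for (m in matrices)
    if (!identical(dimnames(m), nm))
      stop("all matrices must share region ordering")
  if (is.null(years))
    years <- vapply(matrices, function(m) attr(m, "year"), numeric(1))
  structure(list(matrices = matrices, years = years,
                 regions = attr(matrices[[1]], "regions")),
            class = "connectivity_stack")
}

as_array3 <- function(stack) {
  R <- dim(stack$matrices[[1]])[1]
  arr <- array(unlist(stack$matrices), c(R, R, length(stack$matrices)))
  dimnames(arr) <- c(dimnames(stack$matrices[[1]]), list(stack$years))
  arr
}

#' Mean connectivity over the study years
#'
#' Elementwise arithmetic mean of the annual matrices.
#'
#' @param stack a `connectivity_stack`.
#' @return a `connectivity_matrix` (year attribute `"mean"`).
#' @export
mean_connectivity <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  m <- apply(as_array3(stack), c(1, 2), mean)
  structure(m, year = "mean", regions = stack$regions,
            class = c("connectivity_matrix", "matrix"))
}

#' Coefficient of variation of annual connectivity
#'
#' Per-cell sample standard deviation (n - 1 denominator) of the annual
#' series divided by its mean, a measure of temporal volatility of each
#' connection. Cells whose mean is zero (never-realized connections) are
#' masked as `NA` — not 0, not Inf.
#'
#' @param stack a `connectivity_stack` of at least two years.
#' @return a `connectivity_matrix`-classed matrix of CVs.
#' @export
cv_connectivity <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  if (length(stack$matrices) < 2)
    stop("CV requires at least two annual matrices")
  arr <- as_array3(stack)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  cv <- ifelse(m > 0, s / m, NA)
  structure(cv, year = "cv", regions = stack$regions,
            class = c("connectivity_matrix", "matrix"))
}

#' Annual connectivity anomaly matrices
#'
#' Each year's matrix minus the multi-year mean, with a sign classification
#' (+1 increase, -1 decrease, 0 unchanged relative to the mean). Per cell,
#' the anomalies sum to zero across years by construction.
#'
#' @param stack a `connectivity_stack` of at least two years.
#' @return list with `anomalies` (named list of signed matrices) and
#'   `signs` (named list of \{+1, -1, 0\} matrices).
#' @export
anomaly_matrices <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  if (length(stack$matrices) < 2)
    stop("anomalies require at least two annual matrices")
  m <- mean_connectivity(stack)
  anom <- lapply(stack$matrices, function(cm) unclass(cm) - unclass(m))
  names(anom) <- stack$years
  list(anomalies = anom, signs = lapply(anom, sign))
}

#' @export
print.connectivity_matrix <- function(x, digits = 4, ...) {
  yr <- attr(x, "year")
  cat("Connectivity matrix", if (!is.null(yr) && !is.na(yr))
    paste0(" (", yr, ")"), ": ", nrow(x), " x ", ncol(x),
    " regions (north to south)\n", sep = "")
  vals <- x[is.finite(x) & x > 0]
  cat("realized connections: ", sum(is.finite(x) & x > 0),
      "; retention (diagonal) mean: ",
      signif(mean(diag(x), na.rm = TRUE), 3), "\n", sep = "")
  if (length(vals))
    cat("nonzero values: median ", signif(stats::median(vals), digits),
        ", max ", signif(max(vals), digits), "\n", sep = "")
  invisible(x)
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat("Connectivity stack: ", length(x$matrices), " annual matrices (",
      paste(x$years, collapse = ", "), "), ",
      nrow(x$matrices[[1]]), " regions\n", sep = "")
  invisible(x)
}

#' Heatmap of a connectivity matrix
#'
#' Sources as rows (north at top), sinks as columns; cells below the
#' diagonal are equatorward transport, above poleward. Values are drawn on
#' a log10 scale.
#'
#' @param x a `connectivity_matrix`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.connectivity_matrix <- function(x, main = attr(x, "year"), ...) {
  R <- nrow(x)
  z <- log10(pmax(unclass(x), 1e-8))
  graphics::image(seq_len(R), seq_len(R), t(z[R:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "sink region (N to S)",
                  ylab = "source region (S to N)",
                  main = main %||% "", axes = FALSE, ...)
  graphics::axis(1, at = pretty(seq_len(R)))
  graphics::axis(2, at = pretty(seq_len(R)), labels = rev(pretty(seq_len(R))))
  graphics::box()
  invisible(x)
}
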