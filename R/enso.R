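#' Classify the direction of a source-sink connection
#'
#' In this Southern-Hemisphere-like domain, poleward means southward
#' (towards higher `latitude_rank`) and equatorward northward, along the
#' shelf (i.e. among inshore or among offshore regions). Across-shelf
#' connectivity is transport from offshore towards inshore regions;
#' inshore-to-offshore transport is classified separately (reported but
#' excluded from the three directional metrics). A region onto itself is
#' retention.
#'
#' @param source_region,sink_region region ids (vectorized).
#' @param domain the `domain`.
#' @return character vector in `retention`, `poleward`, `equatorward`,
#'   `across_shelf`, `inshore_to_offshore`.
#' @export
classify_direction <- function(source_region, sink_region, domain) {
  stopifnot(inherits(domain, "domain"))
  reg <- domain$regions
  i <- match(source_region, reg$region_id)
  j <- match(sink_region, reg$region_id)
  if (anyNA(i) || anyNA(j)) stop("unknown region id")
  out <- character(length(i))
  same <- i == j
  out[same] <- "retention"
  cross <- !same & reg$band[i] == "offshore" & reg$band[j] == "inshore"
  out[cross] <- "across_shelf"
  in2off <- !same & reg$band[i] == "inshore" & reg$band[j] == "offshore"
  out[in2off] <- "inshore_to_offshore"
  along <- !same & reg$band[i] == reg$band[j]
  out[along & reg$latitude_rank[j] > reg$latitude_rank[i]] <- "poleward"
  out[along & reg$latitude_rank[j] < reg$latitude_rank[i]] <- "equatorward"
  out
}

# R x R character matrix of direction classes, in the matrix's region order
direction_matrix <- function(domain) {
  reg <- domain$regions[order(domain$regions$latitude_rank), ]
  ids <- reg$region_id
  R <- length(ids)
  matrix(classify_direction(rep(ids, times = R), rep(ids, each = R), domain),
         R, R, dimnames = list(source = reg$name, sink = reg$name))
}

#' Default southernmost-region exclusion set
#'
#' The directional analysis excludes the southernmost region groups, whose
#' dispersal directionality differs from the rest of the shelf; by default
#' the two regions of highest `latitude_rank`.
#'
#' @param domain the `domain`.
#' @param n how many southernmost regions to exclude.
#' @return integer vector of region ids.
#' @export
southernmost_regions <- function(domain, n = 2L) {
  reg <- domain$regions
  reg$region_id[order(reg$latitude_rank, decreasing = TRUE)][seq_len(min(n, nrow(reg)))]
}

#' Directional summary of an annual connectivity matrix
#'
#' Averages connectivity over the region pairs of each direction class
#' (poleward, equatorward, across-shelf) whose *source* lies in the
#' configured sectors (default central + southern) minus the excluded
#' southernmost set, and computes the poleward share of realized (nonzero)
#' along-shelf connections:
#' `100 * n_nonzero_poleward / (n_nonzero_poleward + n_nonzero_equatorward)`.
#' The poleward and equatorward percentages are complementary by
#' construction. An all-zero along-shelf set masks the fractions as `NA`.
#'
#' @param matrix a `connectivity_matrix`.
#' @param domain the `domain`.
#' @param source_sectors sectors whose regions count as sources.
#' @param excluded_regions region ids excluded as sources (default the two
#'   southernmost, see [southernmost_regions()]).
#' @param nonzero_eps threshold above which a cell counts as a realized
#'   connection.
#' @param weighted if `TRUE`, fractions weight cells by connectivity value
#'   instead of counting them.
#' @return one-row data frame: `mean_poleward`, `mean_equatorward`,
#'   `mean_across_shelf`, `poleward_fraction`, `equatorward_fraction`,
#'   `n_poleward`, `n_equatorward`.
#' @export
directional_summary <- function(matrix, domain,
                                source_sectors = c("central", "southern"),
                                excluded_regions = southernmost_regions(domain),
                                nonzero_eps = 0, weighted = FALSE) {
  stopifnot(inherits(domain, "domain"))
  reg <- domain$regions[order(domain$regions$latitude_rank), ]
  stopifnot(all(excluded_regions %in% reg$region_id))
  dirs <- direction_matrix(domain)
  src_ok <- reg$sector %in% source_sectors & !(reg$region_id %in% excluded_regions)
  keep <- matrix(src_ok, nrow(reg), nrow(reg))   # row = source
  M <- unclass(matrix)
  cls_mean <- function(cl) {
    sel <- keep & dirs == cl
    if (!any(sel)) return(0)
    mean(M[sel], na.rm = TRUE)
  }
  strength <- function(cl) {
    sel <- keep & dirs == cl & is.finite(M) & M > nonzero_eps
    if (weighted) sum(M[sel]) else sum(sel)
  }
  np <- strength("poleward"); ne <- strength("equatorward")
  pf <- if (np + ne > 0) 100 * np / (np + ne) else NA_real_
  data.frame(mean_poleward = cls_mean("poleward"),
             mean_equatorward = cls_mean("equatorward"),
             mean_across_shelf = cls_mean("across_shelf"),
             poleward_fraction = pf,
             equatorward_fraction = if (is.na(pf)) NA_real_ else 100 - pf,
             n_poleward = np, n_equatorward = ne)
}

#' Regress a yearly connectivity statistic on the climate index
#'
#' Ordinary least squares of per-year values on the yearly index means,
#' either linear or quadratic (the quadratic form captures the U-shaped
#' across-shelf response, with intensification at both index extremes).
#' The p-value is the two-sided slope t-test (linear) or the model F-test
#' (quadratic); r-squared is `1 - SS_res / SS_tot` and is invariant to
#' affine rescaling of the index.
#'
#' @param yearly_values per-year response values.
#' @param yearly_index per-year climate-index means.
#' @param form `"linear"` or `"quadratic"`.
#' @return object of class `index_regression`: list with `form`,
#'   `coefficients`, `r_squared`, `p_value`, `n` and the underlying `lm`
#'   fit.
#' @export
regress_on_index <- function(yearly_values, yearly_index,
                             form = c("linear", "quadratic")) {
  form <- match.arg(form)
  y <- as.numeric(yearly_values); x <- as.numeric(yearly_index)
  stopifnot(length(y) == length(x))
  n <- length(y)
  need <- if (form == "linear") 3 else 4
  if (n < need) stop("need at least ", need, " years for a ", form, " fit")
  if (stats::sd(x) == 0) stop("zero variance in the index")
  fit <- if (form == "linear") stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
  sm <- summary(fit)
  p <- if (form == "linear") sm$coefficients["x", "Pr(>|t|)"] else {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  structure(list(form = form, coefficients = stats::coef(fit),
                 r_squared = sm$r.squared, p_value = unname(p), n = n,
                 fit = fit),
            class = "index_regression")
}

#' @export
print.index_regression <- function(x, ...) {
  cat("Index regression (", x$form, "), n = ", x$n, "\n", sep = "")
  cat("  coefficients: ",
      paste(names(x$coefficients), signif(x$coefficients, 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  r^2 = ", signif(x$r_squared, 3), ", p = ", signif(x$p_value, 3),
      "\n", sep = "")
  invisible(x)
}

#' Exponential-decay fit of mean connectivity against its CV
#'
#' Fits `mean = a * exp(-b * CV)` by nonlinear least squares (log-linear
#' regression supplies the initial values), quantifying how the strongest
#' connections are also the most consistent in time. r-squared is reported
#' on the original (untransformed) scale.
#'
#' @param mean_values positive per-connection mean connectivity values.
#' @param cv_values matching per-connection CVs.
#' @return object of class `decay_fit`: list with `a`, `b`, `r_squared`,
#'   `p_value` (slope test of the log-linear fit), `n`, and the `nls` fit
#'   (`NULL` for the degenerate constant case).
#' @export
fit_mean_vs_cv_decay <- function(mean_values, cv_values) {
  keep <- is.finite(mean_values) & is.finite(cv_values) & mean_values > 0
  m <- as.numeric(mean_values[keep]); cv <- as.numeric(cv_values[keep])
  if (length(m) < 3) stop("need at least 3 (mean, CV) pairs")
  if (stats::sd(cv) <= 1e-10 * (1 + abs(mean(cv)))) {
    # constant CV: the decay rate is unidentifiable; report the flat fit
    return(structure(list(a = mean(m), b = 0, r_squared = 0,
                          p_value = NA_real_, n = length(m), fit = NULL),
                     class = "decay_fit"))
  }
  loglin <- stats::lm(log(m) ~ cv)
  a0 <- exp(stats::coef(loglin)[1]); b0 <- -stats::coef(loglin)[2]
  if (stats::sd(m) == 0) {
    return(structure(list(a = m[1], b = 0, r_squared = NA_real_,
                          p_value = NA_real_, n = length(m), fit = NULL),
                     class = "decay_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ a * exp(-b * cv),
                      start = list(a = unname(a0), b = unname(b0))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear solution
    pred <- a0 * exp(-b0 * cv)
    co <- c(a = unname(a0), b = unname(b0))
  } else {
    co <- stats::coef(fit)
    pred <- stats::predict(fit)
  }
  r2 <- 1 - sum((m - pred)^2) / sum((m - mean(m))^2)
  lcoef <- summary(loglin)$coefficients
  pval <- if ("cv" %in% rownames(lcoef)) lcoef["cv", "Pr(>|t|)"] else NA_real_
  structure(list(a = unname(co["a"]), b = unname(co["b"]), r_squared = r2,
                 p_value = pval, n = length(m), fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential-decay fit mean = a exp(-b CV): a = ", signif(x$a, 4),
      ", b = ", signif(x$b, 4), ", r^2 = ", signif(x$r_squared, 3),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}
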