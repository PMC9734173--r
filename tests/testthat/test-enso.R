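dom <- tiny_domain()   # ranks 1-4; bands in/off/in/off; sectors north x2, south x2

test_that("direction classification follows band and latitude rank", {
  expect_identical(classify_direction(1L, 1L, dom), "retention")
  expect_identical(classify_direction(1L, 3L, dom), "poleward")     # in -> in, south
  expect_identical(classify_direction(3L, 1L, dom), "equatorward")  # in -> in, north
  expect_identical(classify_direction(2L, 3L, dom), "across_shelf") # off -> in
  expect_identical(classify_direction(2L, 1L, dom), "across_shelf")
  expect_identical(classify_direction(1L, 2L, dom), "inshore_to_offshore")
  expect_identical(classify_direction(2L, 4L, dom), "poleward")     # off -> off
  expect_error(classify_direction(1L, 99L, dom), "unknown region")
})

test_that("along-shelf classification is antisymmetric", {
  big <- generate_domain(domain_config(), seed = 2)
  ids <- big$regions$region_id
  pairs <- expand.grid(i = ids, j = ids)
  pairs <- pairs[pairs$i != pairs$j, ]
  cls_ij <- classify_direction(pairs$i, pairs$j, big)
  cls_ji <- classify_direction(pairs$j, pairs$i, big)
  along <- cls_ij %in% c("poleward", "equatorward")
  expect_true(all((cls_ij[along] == "poleward") ==
                  (cls_ji[along] == "equatorward")))
})

test_that("directional summary means match a hand enumeration", {
  reg <- dom$regions[order(dom$regions$latitude_rank), ]
  M <- matrix(0, 4, 4, dimnames = list(source = reg$name, sink = reg$name))
  M[3, 1] <- 0.4   # equatorward (in -> in, source region 3, southern)
  M[4, 2] <- 0.2   # equatorward (off -> off, source 4, southern)
  M[4, 3] <- 0.1   # across-shelf (off -> in, source 4)
  M[1, 3] <- 0.5   # poleward but source region 1 is northern: excluded
  C <- structure(M, year = 1, regions = reg,
                 class = c("connectivity_matrix", "matrix"))
  d <- directional_summary(C, dom, source_sectors = "southern",
                           excluded_regions = integer())
  # southern sources are regions 3 and 4; poleward cells: 3->? none below;
  # equatorward: {3->1, 4->2}; across-shelf: {4->1, 4->3}
  expect_equal(d$mean_equatorward, mean(c(0.4, 0.2)))
  expect_equal(d$mean_across_shelf, mean(c(0.1, 0)))
  expect_equal(d$mean_poleward, 0)
  expect_equal(d$equatorward_fraction, 100)
  expect_equal(d$n_poleward, 0)
  # excluding region 4 drops its cells from every class
  d2 <- directional_summary(C, dom, source_sectors = "southern",
                            excluded_regions = 4L)
  expect_equal(d2$mean_equatorward, 0.4)
  expect_equal(d2$mean_across_shelf, 0)
})

test_that("fractions: all-poleward gives 100%, empty set is masked", {
  reg <- dom$regions[order(dom$regions$latitude_rank), ]
  M <- matrix(0, 4, 4, dimnames = list(source = reg$name, sink = reg$name))
  M[1, 3] <- 0.2; M[2, 4] <- 0.3
  C <- structure(M, year = 1, regions = reg,
                 class = c("connectivity_matrix", "matrix"))
  d <- directional_summary(C, dom, source_sectors = c("northern", "southern"),
                           excluded_regions = integer())
  expect_equal(d$poleward_fraction, 100)
  zero <- structure(matrix(0, 4, 4, dimnames = dimnames(M)), year = 1,
                    regions = reg, class = c("connectivity_matrix", "matrix"))
  dz <- directional_summary(zero, dom, excluded_regions = integer())
  expect_true(is.na(dz$poleward_fraction))
  expect_equal(dz$mean_poleward, 0)
})

test_that("index regression matches the closed-form normal equations", {
  x <- c(20.4, 13.4, -0.2, 5.0, -7.8, -13.6, -0.3, 7.1)
  set.seed(2)
  y <- 3 - 0.5 * x + stats::rnorm(8, 0, 2)
  r <- regress_on_index(y, x, "linear")
  # analytic OLS oracle
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(unname(r$coefficients), c(b0, b1))
  pred <- b0 + b1 * x
  expect_equal(r$r_squared, 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_equal(r$n, 8)
  # exact linear data: r^2 = 1 and exact slope
  rexact <- suppressWarnings(regress_on_index(2 + 3 * x, x, "linear"))
  expect_equal(rexact$r_squared, 1)
  expect_equal(unname(rexact$coefficients[2]), 3)
  # constant response: r^2 = 0
  rconst <- suppressWarnings(regress_on_index(rep(5, 8), x, "linear"))
  expect_equal(rconst$r_squared, 0)
  expect_error(regress_on_index(y, rep(1, 8)), "zero variance")
  expect_error(regress_on_index(y[1:2], x[1:2]), "at least")
})

test_that("r-squared is invariant to affine rescaling of the index", {
  x <- c(-14, -8, -0.2, 5, 7, 13, 20, -3)
  set.seed(5)
  y <- 1 + 0.1 * x + stats::rnorm(8, 0, 0.5)
  r1 <- regress_on_index(y, x, "linear")
  r2 <- regress_on_index(y, 100 + 7 * x, "linear")
  expect_equal(r1$r_squared, r2$r_squared)
  q1 <- regress_on_index(y^2, x, "quadratic")
  q2 <- regress_on_index(y^2, 100 + 7 * x, "quadratic")
  expect_equal(q1$r_squared, q2$r_squared)
})

test_that("quadratic regression recovers an exact U-shape", {
  x <- seq(-20, 20, length.out = 8)
  y <- 0.5 + 0.01 * x + 0.002 * x^2
  q <- suppressWarnings(regress_on_index(y, x, "quadratic"))
  expect_equal(unname(q$coefficients), c(0.5, 0.01, 0.002))
  expect_equal(q$r_squared, 1)
  expect_gt(unname(q$coefficients[3]), 0)      # convex
})

test_that("exponential-decay fit recovers exact and noisy parameters", {
  cv <- seq(0.2, 3, length.out = 30)
  m <- 2 * exp(-cv)
  f <- suppressWarnings(fit_mean_vs_cv_decay(m, cv))
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 1, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # constant means -> b = 0
  fc <- fit_mean_vs_cv_decay(rep(0.4, 10), seq_len(10) / 5)
  expect_equal(fc$b, 0)
  # noisy data: compare against a coarse grid-search refit
  set.seed(8)
  mn <- 1.5 * exp(-0.8 * cv) * exp(stats::rnorm(30, 0, 0.1))
  fn <- fit_mean_vs_cv_decay(mn, cv)
  grid <- expand.grid(a = seq(0.5, 3, by = 0.01), b = seq(0.2, 1.6, by = 0.01))
  sse <- mapply(function(a, b) sum((mn - a * exp(-b * cv))^2), grid$a, grid$b)
  best <- grid[which.min(sse), ]
  expect_equal(fn$a, best$a, tolerance = 0.02)
  expect_equal(fn$b, best$b, tolerance = 0.02)
  expect_error(fit_mean_vs_cv_decay(c(1, 2), c(1, 2)), "at least 3")
})
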