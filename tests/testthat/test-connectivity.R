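dom <- tiny_domain()

# hand-built settlements/schedule for exact tallies
toy_schedule <- function(counts) {
  sc <- dom$seed_cells[seq_along(counts), ]
  sched <- data.frame(cell_id = sc$cell_id, reef_id = sc$reef_id,
                      region_id = sc$region_id, release_hour = 0,
                      count = counts)
  structure(sched, rate = NA, n_days = 1L, seed_cells = sc,
            region_ids = dom$regions$region_id,
            class = c("release_schedule", "data.frame"))
}

toy_matrix <- function(values, year = NA) {
  # values: R x R numeric; wrap as connectivity_matrix in domain order
  reg <- dom$regions[order(dom$regions$latitude_rank), ]
  dimnames(values) <- list(source = reg$name, sink = reg$name)
  structure(values, year = year, regions = reg,
            class = c("connectivity_matrix", "matrix"))
}

test_that("connectivity cells equal settled weight over released count", {
  # region 1 holds cells 1-2; release 100 from each -> 200 released
  sched <- toy_schedule(c(100L, 100L, 50L, 10L))
  settle <- data.frame(source_region = c(1L, 1L, 2L),
                       settle_region = c(2L, 2L, 2L),
                       weight = c(20.5, 20.5, 1))
  C <- build_connectivity_matrix(settle, sched, dom)
  expect_equal(C["n-in-01", "n-off-02"], 41 / 200)   # 0.205
  expect_equal(C["n-off-02", "n-off-02"], 1 / 60)    # retention cell
  expect_true(all(C[, "n-in-01"] == 0, na.rm = TRUE))
  # regions 3-4 released nothing: rows masked
  expect_true(all(is.na(C[3, ])) && all(is.na(C[4, ])))
  # weight conservation: sum(C * releases) = total settled weight
  releases <- attr(C, "releases")
  expect_equal(sum(C * releases, na.rm = TRUE), 42)
  expect_error(build_connectivity_matrix(
    data.frame(source_region = 99L, settle_region = 1L, weight = 1),
    sched, dom), "unknown")
})

test_that("no settlers gives an all-zero matrix over releasing regions", {
  sched <- toy_schedule(c(10L, 10L, 10L, 10L))
  empty <- data.frame(source_region = integer(), settle_region = integer(),
                      weight = numeric())
  C <- build_connectivity_matrix(empty, sched, dom)
  expect_true(all(C[1:2, ] == 0))
})

test_that("stack statistics: mean, CV and anomalies obey their closed forms", {
  set.seed(4)
  R <- 4
  mats <- lapply(1:8, function(k)
    toy_matrix(matrix(stats::runif(R * R), R, R), year = 2009 + k))
  stack <- connectivity_stack(mats)
  m <- mean_connectivity(stack)
  # brute-force re-summation oracle
  brute <- Reduce(`+`, lapply(mats, unclass)) / 8
  expect_equal(unclass(m), brute, ignore_attr = TRUE)
  cv <- cv_connectivity(stack)
  series <- vapply(mats, function(x) x[2, 3], numeric(1))
  expect_equal(cv[2, 3], stats::sd(series) / mean(series))
  an <- anomaly_matrices(stack)
  expect_equal(an$anomalies[["2012"]], unclass(mats[[3]]) - brute,
               ignore_attr = TRUE)
  # per-cell anomalies sum to zero across years
  total <- Reduce(`+`, an$anomalies)
  expect_equal(max(abs(total)), 0, tolerance = 1e-12)
  expect_setequal(unique(as.vector(an$signs[["2010"]])), c(-1, 1))
})

test_that("CV handles constant, two-point and all-zero series correctly", {
  mk <- function(v) toy_matrix(matrix(v, 4, 4))
  const <- connectivity_stack(list(mk(0.3), mk(0.3), mk(0.3)), years = 1:3)
  expect_true(all(cv_connectivity(const) == 0))
  two <- connectivity_stack(list(mk(0.2), mk(0)), years = 1:2)
  expect_equal(cv_connectivity(two)[1, 1], sqrt(2) , tolerance = 1e-12)
  zeros <- connectivity_stack(list(mk(0), mk(0)), years = 1:2)
  expect_true(all(is.na(cv_connectivity(zeros))))
  one <- connectivity_stack(list(mk(0.1)), years = 1)
  expect_error(cv_connectivity(one), "at least two")
  expect_error(anomaly_matrices(one), "at least two")
})

test_that("CV is invariant to uniform rescaling; year order only permutes anomalies", {
  set.seed(9)
  mats <- lapply(1:5, function(k) toy_matrix(matrix(stats::runif(16), 4, 4),
                                             year = k))
  s1 <- connectivity_stack(mats)
  s2 <- connectivity_stack(lapply(mats, function(m)
    toy_matrix(unclass(m) * 3.7, attr(m, "year"))))
  expect_equal(unclass(cv_connectivity(s1)), unclass(cv_connectivity(s2)))
  perm <- c(3, 1, 5, 2, 4)
  s3 <- connectivity_stack(mats[perm])
  expect_equal(unclass(mean_connectivity(s1)), unclass(mean_connectivity(s3)))
  expect_equal(unclass(cv_connectivity(s1)), unclass(cv_connectivity(s3)))
  a1 <- anomaly_matrices(s1)$anomalies
  a3 <- anomaly_matrices(s3)$anomalies
  expect_equal(a3[[1]], a1[[3]])
})

test_that("mismatched matrix dimensions are rejected", {
  small <- structure(matrix(0, 2, 2,
                            dimnames = list(source = c("a", "b"),
                                            sink = c("a", "b"))),
                     year = 1, class = c("connectivity_matrix", "matrix"))
  big <- toy_matrix(matrix(0, 4, 4), year = 2)
  expect_error(connectivity_stack(list(small, big)), "dimension")
})
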