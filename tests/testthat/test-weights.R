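test_that("haversine distance matches closed forms and is symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  # antipodal points: half the circumference, pi * R
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0, 180, radius = 1), pi, tolerance = 1e-12)
  # quarter arc along the equator
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-10)
  set.seed(1)
  for (i in 1:20) {
    p <- c(runif(1, -90, 90), runif(1, -180, 180))
    q <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_equal(haversine_km(p[1], p[2], q[1], q[2]),
                 haversine_km(q[1], q[2], p[1], p[2]))
  }
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
})

test_that("haversine satisfies the triangle inequality on random triples", {
  set.seed(7)
  for (i in 1:50) {
    lat <- runif(3, -90, 90); lon <- runif(3, -180, 180)
    d12 <- haversine_km(lat[1], lon[1], lat[2], lon[2])
    d23 <- haversine_km(lat[2], lon[2], lat[3], lon[3])
    d13 <- haversine_km(lat[1], lon[1], lat[3], lon[3])
    expect_lte(d13, d12 + d23 + 1e-8)
  }
})

test_that("haversine agrees with an independent implementation", {
  skip_if_not_installed("geosphere")
  set.seed(3)
  for (i in 1:10) {
    p <- c(runif(1, -180, 180), runif(1, -90, 90))  # lon, lat
    q <- c(runif(1, -180, 180), runif(1, -90, 90))
    expect_equal(haversine_km(p[2], p[1], q[2], q[1]),
                 geosphere::distHaversine(p, q, r = 6371),
                 tolerance = 1e-6)
  }
})

test_that("spatial distance matrix has the right geometry", {
  n1 <- node_set("a", lat = 10, lon = 10)
  expect_equal(unclass(spatial_distance_matrix(n1))[1, 1], 0)
  # three equatorial points at lon 0 / 90 / 180: arc ratio 1 : 1 : 2
  ns <- node_set(c("a", "b", "c"), lat = c(0, 0, 0), lon = c(0, 90, 180))
  d <- spatial_distance_matrix(ns)
  expect_equal(d["a", "b"], d["b", "c"])
  expect_equal(d["a", "c"], 2 * d["a", "b"], tolerance = 1e-10)
  expect_true(isSymmetric(unclass(d)))
  expect_equal(diag(unclass(d)), setNames(rep(0, 3), c("a", "b", "c")))
  bad <- node_set(c("a", "b"), lat = c(1, NA), lon = c(1, 2))
  expect_error(spatial_distance_matrix(bad), "b")
})

test_that("distance-to-affinity transform: range, diagonal, scale invariance", {
  d <- distance_matrix(matrix(c(0, 4, 4, 0), 2, 2))
  a <- distance_to_affinity(d)
  expect_equal(unclass(a), diag(2), ignore_attr = TRUE)
  d2 <- distance_matrix(matrix(c(0, 25, 40, 25, 0, 100, 40, 100, 0), 3, 3))
  a2 <- distance_to_affinity(d2)
  expect_equal(a2[1, 2], 0.75)  # (100 - 25) / 100
  expect_equal(min(a2), 0)
  expect_equal(max(a2), 1)
  expect_equal(unname(diag(unclass(a2))), rep(1, 3))
  # scale invariance
  a2c <- distance_to_affinity(distance_matrix(unclass(d2) * 37.5))
  expect_equal(unclass(a2), unclass(a2c))
  expect_error(distance_to_affinity(distance_matrix(matrix(0, 3, 3))),
               "degenerate")
})

test_that("affinity invariants hold on generated worlds", {
  for (seed in 1:3) {
    w <- tiny_world(seed = seed)$weights$SoL_aff
    expect_equal(min(w), 0)
    expect_equal(max(w), 1)
    expect_equal(unname(diag(unclass(w))), rep(1, nrow(w)))
    expect_lt(max(abs(unclass(w) - t(unclass(w)))), 1e-12)
  }
})

test_that("adjacency threshold uses strict inequality with a tolerance guard", {
  d <- distance_matrix(matrix(c(0, 999, 1000, 999, 0, 1500, 1000, 1500, 0),
                              3, 3), units = "years")
  a <- adjacency_from_distance(d, 1000)
  expect_equal(a[1, 2], 1)  # 999 < 1000
  expect_equal(a[1, 3], 0)  # 1000 not < 1000
  expect_equal(a[2, 3], 0)
  # within tolerance of the threshold counts as not less
  d2 <- distance_matrix(matrix(c(0, 1000 - 1e-12, 1000 - 1e-12, 0), 2, 2),
                        units = "years")
  expect_equal(adjacency_from_distance(d2, 1000)[1, 2], 0)
  # all far apart -> zero matrix
  expect_true(all(adjacency_from_distance(d, 500) == 0))
})

test_that("adjacency is monotone in the threshold", {
  lang <- make_toy_phylogeny(12, n_colonies = 4, seed = 5)
  a1 <- adjacency_from_distance(lang, 500)
  a2 <- adjacency_from_distance(lang, 2000)
  expect_true(all(a2[a1 == 1] == 1))  # superset of edges
})

test_that("row normalization divides nonzero rows and keeps isolates at zero", {
  a <- matrix(c(0, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  w <- row_normalize(a)
  expect_equal(unclass(w)[1, ], c(n1 = 0, n2 = 0.5, n3 = 0.5))
  expect_equal(unclass(w)[2, ], c(n1 = 1, n2 = 0, n3 = 0))
  expect_equal(unclass(w)[3, ], c(n1 = 0, n2 = 0, n3 = 0))
  k3 <- 1 - diag(3)
  expect_true(all(unclass(row_normalize(k3))[k3 == 1] == 0.5))
  rs <- rowSums(unclass(w))
  expect_true(all(abs(rs) < 1e-12 | abs(rs - 1) < 1e-12))
  expect_error(row_normalize(matrix(c(0, -1, 1, 0), 2, 2)), "nonnegative")
})

test_that("subsetting keeps affinity scale but renormalizes adjacencies", {
  w <- tiny_world(seed = 3)
  aff <- w$weights$SoL_aff
  ids <- rownames(aff)
  expect_equal(unclass(subset_weights(aff, ids)), unclass(aff))
  expect_equal(dim(subset_weights(aff, ids[1])), c(1, 1))
  # affinity values are carried over, not recomputed on the subset
  sub <- subset_weights(aff, ids[1:5])
  expect_equal(unclass(sub), unclass(aff)[ids[1:5], ids[1:5]],
               ignore_attr = TRUE)
  # adjacency: removing a node's only neighbour leaves a zero row
  a <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  a["a", "b"] <- a["b", "a"] <- a["b", "c"] <- a["c", "b"] <- 1
  wn <- row_normalize(a)
  sub2 <- subset_weights(wn, c("a", "c"))
  expect_true(all(unclass(sub2) == 0))
  expect_error(subset_weights(aff, character(0)), "nonempty")
})

test_that("labelled matrix CSV round-trips bit-stably", {
  d <- tiny_world(seed = 8)$lang_dist
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(d, f)
  d2 <- read_matrix_csv(f, units = "years")
  ord <- order(rownames(d))
  expect_equal(unclass(d)[ord, ord], unclass(d2), tolerance = 1e-6,
               ignore_attr = TRUE)
  write_matrix_csv(d2, paste0(f, "2"))
  expect_identical(readLines(f), readLines(paste0(f, "2")))
})
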