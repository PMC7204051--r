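make_square_feature <- function(id, x0, y0, side = 1) {
  ring <- list(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
               c(x0, y0 + side), c(x0, y0))
  list(type = "Feature", properties = list(id = id),
       geometry = list(type = "Polygon", coordinates = list(ring)))
}

test_that("grid queen contiguity has the expected neighbor counts", {
  adj <- grid_queen_contiguity(3, 3)
  deg <- lengths(adj$neighbors)
  expect_equal(sort(unname(deg)), c(3, 3, 3, 3, 5, 5, 5, 5, 8))
  expect_equal(unname(deg[["t00005"]]), 8)   # center cell

  adj2 <- grid_queen_contiguity(2, 2)
  expect_true(all(lengths(adj2$neighbors) == 3))

  adj1 <- grid_queen_contiguity(1, 1)
  expect_equal(lengths(adj1$neighbors), c(t00001 = 0L))
  expect_error(grid_queen_contiguity(0, 3), "positive")
})

test_that("adjacency validation catches asymmetry, self-links, duplicates", {
  expect_error(tract_adjacency(c("a", "a"), list(a = character(0))),
               "duplicate")
  expect_error(tract_adjacency(c("a", "b"),
                               list(a = "b", b = character(0))),
               "asymmetric")
  expect_error(tract_adjacency("a", list(a = "a")), "self-neighbor")
  expect_error(tract_adjacency(c("a", "b"), list(a = "z", b = character(0))),
               "not in id set")
})

test_that("polygon-based queen contiguity matches the grid construction", {
  rows <- 5; cols <- 5
  n <- rows * cols
  ids <- sprintf("t%05d", seq_len(n))
  feats <- vector("list", n)
  k <- 1L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    feats[[k]] <- make_square_feature(ids[k], c - 1, r - 1)
    k <- k + 1L
  }
  gj <- list(type = "FeatureCollection", features = feats)
  adj_poly <- queen_contiguity(gj)
  adj_grid <- grid_queen_contiguity(rows, cols)
  expect_equal(adj_poly$ids, adj_grid$ids)
  expect_equal(adj_poly$neighbors, adj_grid$neighbors)
})

test_that("disjoint polygons are mutual islands", {
  gj <- list(type = "FeatureCollection",
             features = list(make_square_feature("a", 0, 0),
                             make_square_feature("b", 10, 0)))
  adj <- queen_contiguity(gj)
  expect_equal(lengths(adj$neighbors), c(a = 0L, b = 0L))
  expect_warning(w <- row_standardize(adj), "island")
  expect_equal(Matrix::rowSums(w$W), c(a = 0, b = 0))
  expect_equal(w$islands, c("a", "b"))
})

test_that("geojson parsing errors name the offending tract", {
  gj <- list(type = "FeatureCollection",
             features = list(make_square_feature("a", 0, 0),
                             make_square_feature("a", 1, 0)))
  expect_error(queen_contiguity(gj), "duplicate")
  bad <- list(type = "FeatureCollection",
              features = list(list(type = "Feature",
                                   properties = list(id = "x"),
                                   geometry = list(type = "Point",
                                                   coordinates = c(0, 0)))))
  expect_error(queen_contiguity(bad), "x")
})

test_that("row standardization yields unit row sums and zero diagonal", {
  w <- lattice_weights(3, 3)$w
  rs <- Matrix::rowSums(w$W)
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_true(all(Matrix::diag(w$W) == 0))
  # a tract with 4 neighbors would weight each at 0.25; here the corner
  # weights its 3 neighbors at 1/3
  expect_equal(unname(w$W["t00001", w$adjacency$neighbors[["t00001"]]]),
               rep(1 / 3, 3))
})

test_that("eigenvalues are real with spectral radius exactly 1", {
  lat <- lattice_weights(4, 6)
  ev <- lat$ev
  expect_equal(max(ev), 1, tolerance = 1e-12)
  expect_true(all(ev > -1 - 1e-12))
  # the spectrum agrees with a dense eigendecomposition of W itself
  dense <- eigen(as.matrix(lat$w$W), only.values = TRUE)$values
  expect_lt(max(abs(Im(dense))), 1e-10)
  expect_equal(sort(ev), sort(Re(dense)), tolerance = 1e-9)
})

test_that("spatial lag averages neighbors", {
  lat <- lattice_weights(3, 3)
  w <- lat$w
  expect_equal(spatial_lag(w, rep(7, 9)), rep(7, 9))
  # brute-force neighbor averaging oracle
  x <- as.numeric(1:9)
  expected <- vapply(w$ids, function(id) {
    nb <- w$adjacency$neighbors[[id]]
    mean(x[match(nb, w$ids)])
  }, numeric(1))
  expect_equal(spatial_lag(w, x), unname(expected))
  # two mutually adjacent tracts swap values
  pair <- tract_adjacency(c("a", "b"), list(a = "b", b = "a"))
  wp <- row_standardize(pair)
  expect_equal(spatial_lag(wp, c(0, 10)), c(10, 0))
  expect_error(spatial_lag(w, 1:5), "per tract")
})

test_that("adjacency subsetting intersects neighbor sets", {
  adj <- grid_queen_contiguity(4, 4)
  keep <- adj$ids[1:8]
  sub <- subset_adjacency(adj, keep)
  expect_equal(sub$ids, sort(keep, method = "radix"))
  for (id in sub$ids)
    expect_true(all(sub$neighbors[[id]] %in% adj$neighbors[[id]]))
  expect_error(subset_adjacency(adj, "zz"), "unknown")
})

test_that("GAL files round-trip bit-exactly, islands included", {
  adj <- grid_queen_contiguity(3, 4)
  # add an island by keeping a far-away singleton in the id set
  gj <- list(type = "FeatureCollection",
             features = list(make_square_feature("i1", 50, 50)))
  island <- queen_contiguity(gj)
  merged <- tract_adjacency(c(adj$ids, "i1"),
                            c(adj$neighbors, list(i1 = character(0))))
  f1 <- tempfile(fileext = ".gal")
  f2 <- tempfile(fileext = ".gal")
  write_gal(merged, f1)
  back <- read_gal(f1)
  expect_equal(back$ids, merged$ids)
  expect_equal(back$neighbors, merged$neighbors)
  write_gal(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
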