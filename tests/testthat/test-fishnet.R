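test_that("fishnet tiles rectangular boundaries exactly", {
  g <- buildFishnet(boundaryFromExtent(0, 0, 40, 40), cellSize = 20)
  expect_identical(nCells(g), 4L)
  expect_equal(unname(cellAreas(g)), rep(400, 4))

  # partial cell clipped by the boundary edge
  g2 <- buildFishnet(boundaryFromExtent(0, 0, 30, 20), cellSize = 20)
  expect_identical(nCells(g2), 2L)
  expect_equal(sort(unname(cellAreas(g2))), c(200, 400))
  expect_equal(sum(cellAreas(g2)), 600)
})

test_that("clipped cell areas conserve the boundary area", {
  # non-rectangular boundary: a right triangle
  tri <- cbind(x = c(0, 50, 0, 0), y = c(0, 0, 50, 0))
  g <- buildFishnet(tri, cellSize = 10, sliverFrac = 0)
  expect_lt(abs(sum(cellAreas(g)) - 1250) / 1250, 0.001)

  # an L-shaped (concave) boundary
  ell <- cbind(x = c(0, 40, 40, 20, 20, 0, 0), y = c(0, 0, 20, 20, 40, 40, 0))
  g2 <- buildFishnet(ell, cellSize = 20)
  expect_equal(sum(cellAreas(g2)), 1200)
  expect_identical(nCells(g2), 3L)
})

test_that("degenerate boundaries and cell sizes are rejected", {
  expect_error(buildFishnet(cbind(c(0, 0), c(0, 0)), 20), "ring")
  expect_error(buildFishnet(boundaryFromExtent(0, 0, 10, 10), -5), "cellSize")
})

test_that("cell ids are stable and row-major from the grid origin", {
  g <- buildFishnet(boundaryFromExtent(0, 0, 60, 40), cellSize = 20)
  tab <- cellTable(g)
  expect_identical(tab$id, seq_len(6L))
  expect_identical(tab$id[order(tab$row, tab$col)], tab$id)
  g2 <- buildFishnet(boundaryFromExtent(0, 0, 60, 40), cellSize = 20)
  expect_identical(cellTable(g2), tab)
})

test_that("zonal composition counts pixels and partitions cell areas", {
  g <- buildFishnet(boundaryFromExtent(0, 0, 40, 40), cellSize = 20)
  uniform <- LandCoverMap(matrix(1L, 40, 40))
  comp <- zonalComposition(g, uniform)
  expect_equal(unname(classAreas(comp)[, "cropland"]), rep(400, 4))
  expect_true(all(classAreas(comp)[, -1] == 0))

  # toy 4x4-pixel cell with hand-counted mix: 10 cropland + 6 urban
  codes <- matrix(1L, 4, 4)
  codes[cbind(c(1, 1, 2, 3, 4, 4), c(1, 2, 3, 4, 1, 2))] <- 5L
  m <- LandCoverMap(codes)
  g1 <- buildFishnet(boundaryFromExtent(0, 0, 4, 4), cellSize = 4)
  comp1 <- zonalComposition(g1, m)
  expect_equal(unname(classAreas(comp1)[1, c("cropland", "urban")]), c(10, 6))

  # partition conservation on a random map
  m2 <- randomToyMap(40, 40, seed = 3)
  comp2 <- zonalComposition(g, m2)
  expect_equal(rowSums(classAreas(comp2)), comp2@cellArea, tolerance = 1e-12)
})

test_that("composition is invariant to how the map was assembled", {
  # same pixel multiset, two different spatial arrangements within one cell
  g <- buildFishnet(boundaryFromExtent(0, 0, 6, 6), cellSize = 6)
  v <- rep(c(1L, 3L, 5L), each = 12)
  a <- zonalComposition(g, LandCoverMap(matrix(v, 6, 6)))
  b <- zonalComposition(g, LandCoverMap(matrix(rev(v), 6, 6)))
  expect_equal(classAreas(a), classAreas(b))
})

test_that("zonal indicator means reproduce constants and global averages", {
  g <- buildFishnet(boundaryFromExtent(0, 0, 30, 30), cellSize = 10)
  mk <- function(f) {
    s <- lapply(indicatorNames(), function(nm) f())
    names(s) <- indicatorNames()
    IndicatorStack(s)
  }
  const <- mk(function() matrix(7, 30, 30))
  expect_true(all(abs(zonalIndicatorMeans(g, const) - 7) < 1e-12))

  set.seed(4)
  rnd <- mk(function() matrix(rnorm(900), 30, 30))
  zm <- zonalIndicatorMeans(g, rnd)
  # count-weighted mean of cell means equals the global pixel mean
  counts <- zonalComposition(g, LandCoverMap(matrix(1L, 30, 30)))@cellArea
  for (j in seq_len(8)) {
    expect_equal(sum(zm[, j] * counts) / sum(counts),
                 mean(rnd@surfaces[[j]]), tolerance = 1e-12)
  }
})

test_that("two-pixel cell arithmetic and empty cells behave as documented", {
  g <- buildFishnet(boundaryFromExtent(0, 0, 2, 1), cellSize = 1)
  s <- lapply(indicatorNames(), function(nm) matrix(c(1, 3), 1, 2))
  names(s) <- indicatorNames()
  # both pixels in separate 1-km cells: means are the pixel values
  zm <- zonalIndicatorMeans(g, IndicatorStack(s))
  expect_equal(unname(zm[, "GDP"]), c(1, 3))

  # one fully-nodata cell is dropped from composition with a warning
  codes <- matrix(1L, 1, 2)
  codes[1, 2] <- NA_integer_
  expect_warning(comp <- zonalComposition(g, LandCoverMap(codes)), "dropped")
  expect_identical(comp@cellIds, 1L)
})

test_that("geojson boundaries load as closed rings", {
  p <- file.path(tempdir(), "b.geojson")
  writeLines('{"type":"FeatureCollection","features":[{"type":"Feature",
    "properties":{},"geometry":{"type":"Polygon",
    "coordinates":[[[0,0],[40,0],[40,40],[0,40],[0,0]]]}}]}', p)
  ring <- readBoundaryGeoJSON(p)
  expect_identical(ring[1, ], ring[nrow(ring), ])
  g <- buildFishnet(ring, cellSize = 20)
  expect_identical(nCells(g), 4L)
})
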