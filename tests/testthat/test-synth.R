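test_that("config validation rejects malformed generator settings", {
  expect_error(synthConfig(proportions = c(0.5, 0.5, 0, 0, 0, 0.1)), "sum to 1")
  expect_error(synthConfig(proportions = c(-0.1, 1.1, 0, 0, 0, 0)), "non-negative")
  expect_error(synthConfig(clumping = 1.5), "clumping")
  expect_error(synthConfig(corLength = 0), "corLength")
  expect_error(synthConfig(urbanRate = 2), "urbanRate")
})

test_that("degenerate single-class landscape is uniform with one patch", {
  cfg <- synthConfig(seed = 11, proportions = c(1, 0, 0, 0, 0, 0),
                     clumping = 0.7)
  m <- generateLandcover(cfg, c(0, 0, 30, 30), 1)
  expect_true(all(m@codes == landClasses()[["cropland"]]))
  expect_identical(labelPatches(m@codes, 1, 8), 1L)
})

test_that("unclumped landscapes realize requested proportions within 2 points", {
  prop <- c(0.30, 0.15, 0.30, 0.05, 0.10, 0.10)
  for (s in 1:20) {
    cfg <- synthConfig(seed = s, proportions = prop, clumping = 0)
    m <- generateLandcover(cfg, c(0, 0, 100, 100), 1)
    realized <- tabulate(m@codes, 6) / length(m@codes)
    expect_lt(max(abs(realized - prop)), 0.02)
  }
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- synthConfig(seed = 42, clumping = 0.6)
  ext <- c(0, 0, 50, 50)
  expect_identical(generateLandcover(cfg, ext, 1)@codes,
                   generateLandcover(cfg, ext, 1)@codes)
  s1 <- generateIndicators(cfg, ext, 1)
  s2 <- generateIndicators(cfg, ext, 1)
  expect_identical(s1@surfaces, s2@surfaces)
  m <- generateLandcover(cfg, ext, 1)
  e1 <- evolveLandcover(m, cfg, steps = 3)
  e2 <- evolveLandcover(m, cfg, steps = 3)
  expect_identical(lapply(e1, slot, "codes"), lapply(e2, slot, "codes"))
})

test_that("indicator stack has the 8 named surfaces and smoothing works", {
  cfg <- synthConfig(seed = 5, corLength = 2)
  st <- generateIndicators(cfg, c(0, 0, 60, 60), 1)
  expect_identical(names(st@surfaces), indicatorNames())
  expect_length(st@surfaces, 8L)
  # lag-1 autocorrelation increases with correlation length
  lag1 <- function(m) cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
  rough <- generateIndicators(synthConfig(seed = 5, corLength = 1),
                              c(0, 0, 60, 60), 1)
  smooth <- generateIndicators(synthConfig(seed = 5, corLength = 8),
                               c(0, 0, 60, 60), 1)
  expect_gt(lag1(smooth@surfaces$GDP), lag1(rough@surfaces$GDP))
  # heavy-smoothing limit: the surface is locally near-constant, i.e. the
  # variance of neighbour differences vanishes relative to the field's
  heavy <- generateIndicators(synthConfig(seed = 5, corLength = 40),
                              c(0, 0, 60, 60), 1)@surfaces$GDP
  localVar <- var(as.numeric(heavy[, -1] - heavy[, -ncol(heavy)]))
  expect_lt(localVar / var(as.numeric(heavy)), 0.01)
})

test_that("urbanization converts the 4-adjacent cropland frontier", {
  # 3x3 toy: urban center, cropland elsewhere; rate 1, one step
  codes <- matrix(landClasses()[["cropland"]], 3, 3)
  codes[2, 2] <- landClasses()[["urban"]]
  m <- LandCoverMap(codes)
  cfg <- synthConfig(seed = 1, urbanRate = 1)
  out <- evolveLandcover(m, cfg, steps = 1)[[2]]
  urban <- out@codes == landClasses()[["urban"]]
  expect_identical(sum(urban), 5L)  # center + 4-neighbours, not diagonals
  expect_true(all(urban[cbind(c(1, 2, 2, 3, 2), c(2, 1, 3, 2, 2))]))

  # rate 0: every step identical to the input
  same <- evolveLandcover(m, synthConfig(seed = 1, urbanRate = 0), steps = 3)
  for (x in same) expect_identical(x@codes, codes)

  # no urban nucleus: unchanged at any rate
  noUrban <- LandCoverMap(matrix(landClasses()[["cropland"]], 3, 3))
  out2 <- evolveLandcover(noUrban, cfg, steps = 2)
  for (x in out2) expect_identical(x@codes, noUrban@codes)
})

test_that("urban area is non-decreasing along any evolution sequence", {
  for (s in c(2, 9, 23)) {
    cfg <- synthConfig(seed = s, clumping = 0.4, urbanRate = 0.3)
    m <- generateLandcover(cfg, c(0, 0, 40, 40), 1)
    seqs <- evolveLandcover(m, cfg, steps = 4)
    urban <- vapply(seqs, function(x)
      sum(x@codes == landClasses()[["urban"]]), integer(1))
    expect_true(all(diff(urban) >= 0))
  }
})

test_that("ascii-grid round trip preserves maps and sidecar provenance", {
  cfg <- synthConfig(seed = 8, clumping = 0.5)
  m <- generateLandcover(cfg, c(0, 0, 25, 20), 1)
  m@codes[1, 1:3] <- NA_integer_
  p <- file.path(tempdir(), "map.asc")
  writeAsciiGrid(m, p, config = cfg)
  back <- readAsciiGrid(p)
  expect_identical(back@codes, m@codes)
  expect_equal(back@res, m@res)
  side <- yaml::read_yaml(sub("asc$", "yml", p))
  expect_equal(side$seed, 8)
})
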