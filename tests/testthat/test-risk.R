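makeMetrics <- function(cells) {
  # cells: list of data.frames with class, area, E; cell area = sum of areas
  do.call(rbind, lapply(seq_along(cells), function(k) {
    df <- cells[[k]]
    data.frame(cell_id = k, class = df$class, n = 1L, area_km2 = df$area,
               cell_area_km2 = sum(df$area), C = 0, S = 0, D = 0, E = df$E)
  }))
}

test_that("LERI is the composition-weighted mean of E x F", {
  # single class filling the cell with E = F = 1
  met <- makeMetrics(list(data.frame(class = "cropland", area = 400, E = 1)))
  Fm <- matrix(1, 1, 6, dimnames = list("1", names(landClasses())))
  expect_equal(unname(leriIndex(met, Fm)), 1)

  # two classes half/half with E*F = 2 and 4 -> weighted mean 3
  met2 <- makeMetrics(list(data.frame(class = c("cropland", "urban"),
                                      area = c(200, 200), E = c(2, 4))))
  expect_equal(unname(leriIndex(met2, Fm)), 3)

  # zero disturbance gives zero risk
  met3 <- makeMetrics(list(data.frame(class = c("water", "unused"),
                                      area = c(100, 300), E = c(0, 0))))
  expect_equal(unname(leriIndex(met3, Fm)), 0)
})

test_that("LERI matches a brute-force term-by-term oracle on random cells", {
  set.seed(61)
  for (rep in 1:10) {
    m <- randomToyMap(30, 30, seed = 600 + rep)
    g <- buildFishnet(boundaryFromExtent(0, 0, 30, 30), cellSize = 10)
    met <- cellTypeMetrics(g, m)
    MN <- setNames(runif(9, 0.5, 1.5), 1:9)
    Fm <- vulnerabilityIndex(MN)
    expect_equal(leriIndex(met, Fm), bruteLERI(met, Fm), tolerance = 1e-12)
  }
})

test_that("LERI is bounded by max E*F and reduces to E*EV for uniform cells", {
  m <- randomToyMap(20, 20, seed = 71)
  g <- buildFishnet(boundaryFromExtent(0, 0, 20, 20), cellSize = 10)
  met <- cellTypeMetrics(g, m)
  Fm <- vulnerabilityIndex(setNames(rep(1, 4), 1:4))
  L <- leriIndex(met, Fm)
  for (k in 1:4) {
    rows <- met[met$cell_id == k, ]
    ef <- rows$E * Fm[as.character(k), rows$class]
    expect_lte(L[[as.character(k)]], max(ef) + 1e-12)
  }

  # closed-form limit: MN = 1 and one uniform class per cell
  uni <- LandCoverMap(matrix(3L, 20, 20))
  metU <- cellTypeMetrics(g, uni)
  LU <- leriIndex(metU, vulnerabilityIndex(setNames(rep(1, 4), 1:4)))
  Egrass <- metU$E[metU$class == "grassland"]
  expect_equal(unname(LU), Egrass * empiricalVulnerability()[["grassland"]])
})

test_that("LERI is invariant to class relabeling with matched EV", {
  m <- randomToyMap(20, 20, seed = 81, prop = c(0.5, 0.5, 0, 0, 0, 0))
  swapped <- LandCoverMap(ifelse(m@codes == 1L, 2L, 1L),
                          m@xmin, m@ymin, m@res)
  g <- buildFishnet(boundaryFromExtent(0, 0, 20, 20), cellSize = 10)
  MN <- setNames(rep(1, 4), 1:4)
  EV1 <- empiricalVulnerability()
  EV2 <- EV1; EV2[["cropland"]] <- EV1[["woodland"]]; EV2[["woodland"]] <- EV1[["cropland"]]
  L1 <- leriIndex(cellTypeMetrics(g, m), vulnerabilityIndex(MN, EV1), EV1)
  L2 <- leriIndex(cellTypeMetrics(g, swapped), vulnerabilityIndex(MN, EV2), EV2)
  expect_equal(L1, L2)
})

test_that("fixed-break classification applies the printed thresholds", {
  expect_identical(as.character(classifyRisk(0.5999)), "low")
  expect_identical(as.character(classifyRisk(0.60)), "medium-low")
  expect_identical(as.character(classifyRisk(1.3443)), "medium")
  expect_identical(as.character(classifyRisk(2.3999)), "medium-high")
  expect_identical(as.character(classifyRisk(2.40)), "high")
  expect_error(classifyRisk(-0.1), ">= 0")
  expect_error(classificationScheme(c(1, 1)), "increasing")
})

test_that("jenks breaks separate well-separated groups and reject degenerates", {
  sch <- jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_equal(sch$breaks, 10)
  cl <- classifyRisk(c(1, 2, 3, 10, 11, 12), sch)
  expect_identical(as.integer(cl), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(jenksBreaks(rep(5, 10), 2), "distinct")
})

test_that("jenks dynamic program matches the exhaustive-partition oracle", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 2)
    if (length(unique(x)) < k) next
    sch <- jenksBreaks(x, k)
    oracle <- jenksOracle(x, k)
    # optimal SSE is unique even when the argmin partition is not
    cl <- classifyRisk(x, sch)
    sseOf <- function(breaks) {
      cls <- findInterval(sort(x), breaks) + 1
      sum(vapply(split(sort(x), cls), function(v) sum((v - mean(v))^2),
                 numeric(1)))
    }
    expect_equal(sseOf(sch$breaks), oracle$sse, tolerance = 1e-9)
  }
})

test_that("risk rate of change is the annualized relative change", {
  expect_equal(riskRateOfChange(1.0, 0.8, 5), -4)
  expect_equal(riskRateOfChange(1.5, 1.5, 5), 0)
  expect_equal(riskRateOfChange(1, 2, 1), 100)
  expect_error(riskRateOfChange(1, 2, 0), "deltaT")
  expect_warning(out <- riskRateOfChange(c(0, 1), c(1, 1), 5), "NA")
  expect_true(is.na(out[1]) && out[2] == 0)
})

test_that("coefficient of variation uses sample SD and is scale-invariant", {
  expect_equal(coefficientOfVariation(c(1, 1, 1, 1)), 0)
  expect_equal(coefficientOfVariation(c(1, 1, 1, 1, 2)),
               sd(c(1, 1, 1, 1, 2)) / 1.2)
  expect_equal(round(coefficientOfVariation(c(1, 1, 1, 1, 2)), 4), 0.3727)
  set.seed(99)
  x <- runif(6, 0.5, 2)
  expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x))
  expect_error(coefficientOfVariation(1), "length >= 2")
})

test_that("temporal statistics attach to the panel rowData", {
  L <- cbind(y2000 = c(1, 2, 1), y2005 = c(1, 1.5, 1.2),
             y2010 = c(1, 1.2, 0.9))
  rownames(L) <- 1:3
  panel <- addTemporalStats(RiskPanel(L))
  rd <- SummarizedExperiment::rowData(panel)
  expect_equal(unname(rd$RRC[1]), 0)
  expect_equal(unname(rd$RRC[2]), (1.2 - 2) / 2 / 10 * 100)
  expect_equal(unname(rd$RRC_y2000_y2005[2]), (1.5 - 2) / 2 / 5 * 100)
  expect_equal(unname(rd$CV[1]), 0)
  expect_equal(unname(rd$CV[3]), sd(c(1, 1.2, 0.9)) / mean(c(1, 1.2, 0.9)))
})
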