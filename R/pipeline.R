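# End-to-end orchestration: grid -> composition -> patch metrics ->
# vulnerability -> LERI -> classification -> temporal statistics ->
# key areas -> transfer matrices, with CSV/JSON outputs and a run manifest.

#' Assess landscape ecological risk over a map series
#'
#' Runs the full per-period computation and assembles a [RiskPanel-class].
#' Vulnerability is dynamic: the adjustment factor MN is computed per period
#' from that period's indicator stack (a single stack is recycled with a
#' note, making MN static).
#'
#' @param maps named list of [LandCoverMap-class] objects (names = years).
#' @param indicators an [IndicatorStack-class], or a named list of stacks
#'   parallel to \code{maps}; \code{NULL} fixes MN = 1 (static empirical
#'   vulnerability).
#' @param grid a [RiskGrid-class]; built from the maps' shared extent at
#'   \code{cellSize} when omitted.
#' @param cellSize fishnet cell edge in km (default 20), used when
#'   \code{grid} is NULL.
#' @param weightMode "fixed" published indicator weights or "entropy".
#' @param weights [disturbanceWeights()].
#' @param connectivity patch connectivity, 4 or 8.
#' @param EV empirical class vulnerability ranks.
#' @return List: \code{panel} ([RiskPanel-class], temporal stats attached
#'   when >= 2 periods), \code{grid}, \code{metrics} (per period),
#'   \code{vulnerability} (per period), \code{composition} (per period).
#' @export
assessRisk <- function(maps, indicators = NULL, grid = NULL, cellSize = 20,
                       weightMode = c("fixed", "entropy"),
                       weights = disturbanceWeights(), connectivity = 8L,
                       EV = empiricalVulnerability()) {
  weightMode <- match.arg(weightMode)
  if (!length(maps)) stop("need at least one land-cover map")
  if (is.null(names(maps))) names(maps) <- paste0("t", seq_along(maps))
  for (m in maps[-1]) if (!sameRegistry(maps[[1]], m))
    stop(registryDiff(maps[[1]], m))
  if (is.null(grid)) {
    ext <- mapExtent(maps[[1]])
    grid <- buildFishnet(boundaryFromExtent(ext[1], ext[2], ext[3], ext[4]),
                         cellSize = cellSize)
  }
  if (is(indicators, "IndicatorStack"))
    indicators <- setNames(rep(list(indicators), length(maps)), names(maps))

  leriCols <- vector("list", length(maps))
  metricsList <- vulnList <- compList <- vector("list", length(maps))
  names(metricsList) <- names(vulnList) <- names(compList) <- names(maps)
  for (t in seq_along(maps)) {
    comp <- zonalComposition(grid, maps[[t]])
    met <- cellTypeMetrics(grid, maps[[t]], weights = weights,
                           connectivity = connectivity, composition = comp)
    cid <- as.character(comp@cellIds)
    if (is.null(indicators)) {
      vul <- list(MN = setNames(rep(1, length(cid)), cid), w = NULL)
      Fmat <- vulnerabilityIndex(vul$MN, EV)
    } else {
      raw <- zonalIndicatorMeans(grid, indicators[[t]])[cid, , drop = FALSE]
      vul <- computeVulnerability(raw, weightMode = weightMode,
                                  orientations = indicators[[t]]@orientations,
                                  EV = EV)
      names(vul$MN) <- cid
      Fmat <- vulnerabilityIndex(vul$MN, EV)
    }
    leriCols[[t]] <- leriIndex(met, Fmat, EV)
    metricsList[[t]] <- met
    vulnList[[t]] <- vul
    compList[[t]] <- comp
  }
  ids <- Reduce(intersect, lapply(leriCols, names))
  L <- do.call(cbind, lapply(leriCols, `[`, ids))
  colnames(L) <- names(maps)
  panel <- RiskPanel(L, cellArea = cellAreas(grid)[ids])
  if (ncol(L) >= 2L) panel <- addTemporalStats(panel)
  list(panel = panel, grid = grid, metrics = metricsList,
       vulnerability = vulnList, composition = compList)
}

#' Summarize a panel by region
#'
#' Per-region mean LERI per period, risk-class shares per period (percent,
#' summing to 100 within region-period), mean RRC per window, and key-area
#' counts. Regions are given as a label per cell; cells without a label are
#' reported as "unassigned".
#'
#' @param panel a [RiskPanel-class].
#' @param regions character/factor per cell (NA = unassigned), or NULL for
#'   a single whole-study region.
#' @param scheme a [classificationScheme()] for the class shares.
#' @param mask optional \code{keyAreaMask} from [keyAreas()].
#' @return List of data.frames: meanLERI, classShares, meanRRC, keyCounts.
#' @export
summarizeRisk <- function(panel, regions = NULL,
                          scheme = classificationScheme(), mask = NULL) {
  L <- leriValues(panel)
  if (is.null(regions)) regions <- rep("all", nrow(L))
  regions <- as.character(regions)
  regions[is.na(regions)] <- "unassigned"
  reg <- factor(regions)
  meanLERI <- do.call(rbind, lapply(levels(reg), function(r) {
    data.frame(region = r, period = colnames(L),
               mean_LERI = colMeans(L[reg == r, , drop = FALSE]),
               n_cells = sum(reg == r), row.names = NULL)
  }))
  classShares <- do.call(rbind, lapply(levels(reg), function(r) {
    do.call(rbind, lapply(colnames(L), function(p) {
      cl <- classifyRisk(L[reg == r, p], scheme)
      sh <- 100 * table(cl) / length(cl)
      data.frame(region = r, period = p, level = names(sh),
                 share_pct = as.numeric(sh), row.names = NULL)
    }))
  }))
  rd <- SummarizedExperiment::rowData(panel)
  rrcCols <- grep("^RRC", colnames(rd), value = TRUE)
  meanRRC <- if (length(rrcCols)) do.call(rbind, lapply(levels(reg), function(r) {
    data.frame(region = r, window = rrcCols,
               mean_RRC = vapply(rrcCols, function(cc)
                 mean(rd[[cc]][reg == r], na.rm = TRUE), numeric(1)),
               row.names = NULL)
  })) else NULL
  keyCounts <- if (!is.null(mask)) do.call(rbind, lapply(levels(reg), function(r) {
    f <- mask$flags[reg == r, ]
    data.frame(region = r, stable_high_risk = sum(f$stable_high_risk),
               reduction_lagged = sum(f$reduction_lagged),
               risk_unstable = sum(f$risk_unstable),
               key_union = sum(f$key_union), n_cells = nrow(f),
               row.names = NULL)
  })) else NULL
  list(meanLERI = meanLERI, classShares = classShares, meanRRC = meanRRC,
       keyCounts = keyCounts)
}

#' Run the full pipeline from a configuration
#'
#' Either generates a synthetic multi-year study (config$synthetic) or loads
#' land-cover/indicator rasters from .asc paths (config$landcover, a named
#' year -> path list; config$indicators, year -> directory of
#' \code{<indicator>.asc}). Writes grid, composition, metrics, vulnerability,
#' risk panel, key-area and transfer-matrix CSVs plus a JSON run manifest to
#' \code{outDir}, and returns the in-memory results.
#'
#' @param config list or path to a YAML file. Recognized fields: seed,
#'   cellSize (km, default 20), keyQuantile (default 0.15), weightMode
#'   ("fixed"/"entropy"), connectivity (4/8), breaks (fixed classification
#'   breaks), synthetic (list: extent, res, nPeriods, proportions, clumping,
#'   corLength, urbanRate), landcover, indicators.
#' @param outDir output directory (created); NULL skips writing.
#' @return Invisibly, the [assessRisk()] bundle plus \code{mask},
#'   \code{transfers}, \code{summary} and \code{manifest}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  cellSize <- config$cellSize %||% 20
  q <- config$keyQuantile %||% 0.15
  weightMode <- config$weightMode %||% "fixed"
  connectivity <- as.integer(config$connectivity %||% 8L)
  scheme <- classificationScheme(unlist(config$breaks %||%
                                          c(0.60, 1.18, 1.72, 2.40)))

  if (!is.null(config$synthetic)) {
    s <- config$synthetic
    cfg <- synthConfig(seed = seed,
                       proportions = unlist(s$proportions %||%
                         c(0.30, 0.15, 0.30, 0.05, 0.10, 0.10)),
                       clumping = s$clumping %||% 0.5,
                       corLength = s$corLength %||% 8,
                       urbanRate = s$urbanRate %||% 0.10,
                       steps = (s$nPeriods %||% 5L) - 1L)
    extent <- unlist(s$extent %||% c(0, 0, 200, 200))
    res <- s$res %||% 1
    base <- generateLandcover(cfg, extent, res)
    maps <- evolveLandcover(base, cfg)
    names(maps) <- paste0("y", seq(2000, by = 5, length.out = length(maps)))
    # one indicator stack per period so MN is genuinely dynamic
    stacks <- lapply(seq_along(maps), function(t) {
      generateIndicators(synthConfig(seed = seed + 10L * t,
                                     proportions = cfg$proportions,
                                     clumping = cfg$clumping,
                                     corLength = cfg$corLength),
                         extent, res)
    })
    names(stacks) <- names(maps)
  } else if (!is.null(config$landcover)) {
    maps <- lapply(config$landcover, readAsciiGrid, categorical = TRUE)
    stacks <- if (!is.null(config$indicators))
      lapply(config$indicators, function(dir) {
        surf <- lapply(indicatorNames(), function(nm) {
          readAsciiGrid(file.path(dir, paste0(nm, ".asc")),
                        categorical = FALSE)$values
        })
        names(surf) <- indicatorNames()
        g <- readAsciiGrid(file.path(dir, paste0(indicatorNames()[1], ".asc")),
                           categorical = FALSE)
        IndicatorStack(surf, xmin = g$xmin, ymin = g$ymin, res = g$res)
      })
    else NULL
  } else stop("config must provide either 'synthetic' or 'landcover'")

  years <- suppressWarnings(as.numeric(gsub("[^0-9]", "", names(maps))))
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")

  bundle <- assessRisk(maps, indicators = stacks, cellSize = cellSize,
                       weightMode = weightMode, connectivity = connectivity)
  panel <- bundle$panel
  singleYear <- ncol(leriValues(panel)) < 2L
  if (singleYear)
    message("single time point: RRC, CV and key areas skipped")
  mask <- if (!singleYear) keyAreas(panel, q = q) else NULL
  transfers <- if (!singleYear)
    transferMatrix(maps[[1]], maps[[length(maps)]]) else NULL
  summary <- summarizeRisk(panel, scheme = scheme, mask = mask)

  manifest <- list(
    package = "leriscape",
    version = as.character(utils::packageVersion("leriscape")),
    seed = seed, cellSize = cellSize, keyQuantile = q,
    weightMode = weightMode, connectivity = connectivity,
    breaks = scheme$breaks,
    disturbanceWeights = as.list(disturbanceWeights()),
    empiricalVulnerability = as.list(empiricalVulnerability()),
    fixedIndicatorWeights = as.list(fixedIndicatorWeights()),
    periods = names(maps), nCells = nrow(leriValues(panel)),
    configDigest = digestConfig(config))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGridCSV(bundle$grid, file.path(outDir, "grid.csv"))
    L <- leriValues(panel)
    wide <- data.frame(cell_id = rownames(L), check.names = FALSE)
    for (p in colnames(L)) {
      wide[[paste0("LERI_", p)]] <- L[, p]
      wide[[paste0("class_", p)]] <- as.character(classifyRisk(L[, p], scheme))
    }
    rd <- SummarizedExperiment::rowData(panel)
    for (cc in grep("^RRC|^CV$", colnames(rd), value = TRUE))
      wide[[cc]] <- rd[[cc]]
    write.csv(wide, file.path(outDir, "risk_panel.csv"), row.names = FALSE)
    for (p in names(bundle$metrics))
      write.csv(bundle$metrics[[p]],
                file.path(outDir, paste0("metrics_", p, ".csv")),
                row.names = FALSE)
    if (!is.null(mask)) {
      write.csv(mask$flags, file.path(outDir, "key_areas.csv"),
                row.names = FALSE)
      jsonlite::write_json(mask[c("counts", "overlaps", "unionCount",
                                  "nCells", "unionSharePct")],
                           file.path(outDir, "key_areas_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(transfers)) {
      write.csv(as.data.frame(unclass(transfers)),
                file.path(outDir, "transfer_matrix.csv"))
      write.csv(transferLong(transfers),
                file.path(outDir, "transfer_long.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(c(bundle, list(mask = mask, transfers = transfers,
                           summary = summary, manifest = manifest)))
}

digestConfig <- function(config) {
  # order-stable fingerprint without external digest packages
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %% 2^31
}
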