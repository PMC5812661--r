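#' End-to-end simulated-cohort pipeline
#'
#' Ties the stages together: cohort simulation (per-animal ground-truth
#' trajectories), per-animal digital phantoms, acquisition simulation for
#' the four contrasts, voxel-wise map fitting, ROI statistics, slice
#' volumetry, group summaries and the statistics layer. Everything is
#' driven by one seed, so a rerun with the same configuration reproduces
#' identical outputs.
#'
#' @name pipeline
NULL

.pipelineDefaults <- function() list(
  seed = 1L,
  snr = 50,                 # single-average SNR of the S0 = 1000 signal
  contrasts = c("ir_truefisp", "multi_echo", "dwi", "mt_flash"),
  cohort = cohortSpec(),
  phantomDim = c(24L, 24L), # map-fitting slice grid
  nVessels = 2L,
  vesselRadius = 1.2,
  roiRadius = 2.2,
  nRois = 3L,
  volumetryDim = c(40L, 40L, 18L),
  volumetryVoxel = c(0.5, 0.5),
  volumetrySliceThickness = 1.0,
  outputDir = NULL
)

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected by name before any stage runs.
#'
#' @param ... overrides of the defaults: `seed`, `snr`, `contrasts`,
#'   `cohort`, `phantomDim`, `nVessels`, `vesselRadius`, `roiRadius`,
#'   `nRois`, `volumetryDim`, `volumetryVoxel`,
#'   `volumetrySliceThickness`, `outputDir`
#' @return list of class `pipelineConfig`
#' @export
pipelineConfig <- function(...) {
  cfg <- .pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration entries must be named")
  cfg[names(over)] <- over
  stopifnot(cfg$snr > 0, cfg$seed == as.integer(cfg$seed),
            inherits(cfg$cohort, "cohortSpec"),
            all(cfg$contrasts %in% .CONTRASTS))
  structure(cfg, class = "pipelineConfig")
}

# truth row vector for one animal/day -> tissue parameter list;
# parameters censored on this day fall back to defaults (they are not
# measured either, so the value never enters the output)
.truthToTissue <- function(vals) {
  gv <- function(p, dflt) if (is.na(vals[p])) dflt else unname(vals[p])
  tissueTruth(
    T1 = gv("T1", 1000), T2 = gv("T2", 30),
    ADC = gv("ADC", 1.5) * 1e-3,     # table units 1e-3 mm^2/s -> mm^2/s
    MTR = gv("MTR", 66) / 100,       # percent -> fraction
    S0 = 1000, M0 = 1000, INV = 1.95, N = 0)
}

.measureMaps <- function(phantom, rois, contrasts, sigma, seed) {
  out <- list()
  mask <- liverMask(phantom)
  for (ci in seq_along(contrasts)) {
    ck <- contrasts[ci]
    meta <- protocolMeta(ck)
    series <- simulateAcquisitions(phantom, meta, sigma = sigma,
                                   seed = .subSeed(seed, ci))
    if (ck == "ir_truefisp") {
      fit <- fitT1Map(series, mask = mask)
      out$T1 <- roiStatistic(parameterMaps(fit)$T1, rois)$mean
    } else if (ck == "multi_echo") {
      fit <- fitT2Map(series, mask = mask)
      out$T2 <- roiStatistic(parameterMaps(fit)$T2, rois)$mean
    } else if (ck == "dwi") {
      sigmaHat <- estimateBackgroundNoise(series)
      map <- fitParameterMaps(series, mask = mask,
                              noise = sigmaHat * sqrt(pi / 2))
      out$ADC <- roiStatistic(map, rois)$mean * 1e3  # -> 1e-3 mm^2/s
    } else if (ck == "mt_flash") {
      map <- fitParameterMaps(series, mask = mask)
      out$MTR <- roiStatistic(map, rois)$mean
    }
  }
  out
}

#' Run the full simulate-fit-summarize pipeline
#'
#' For every animal and measurement day of the simulated cohort, builds a
#' phantom slice carrying that animal's ground-truth tissue parameters,
#' simulates the four protocol acquisitions at the configured SNR, fits
#' the parametric maps, reads them out with three auto-placed vessel-free
#' ROIs, and performs slice-summation volumetry on a separate 3D phantom
#' scaled to the animal's true volume trajectory. The measured long table
#' is then summarized per group and pushed through the statistics layer.
#'
#' @param config a [pipelineConfig()]
#' @return list: `truth` (simulated ground-truth cohort), `measured`
#'   (pipeline-measured long table), `summary` ([groupSummary()] of the
#'   measured table), `stats` (ANOVA per MR parameter, volume
#'   correlations, day-1 logistic regression), `manifest`
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  t0 <- Sys.time()
  cohort <- simulateCohort(config$cohort, seed = .subSeed(config$seed, 0))
  truth <- cohort$table
  sigma <- 1000 / config$snr
  voxArea <- prod(config$volumetryVoxel)

  rows <- list()
  animals <- cohort$animals$animal_id
  for (ai in seq_along(animals)) {
    id <- animals[ai]
    tr <- truth[truth$animal_id == id, ]
    days <- sort(unique(tr$day))

    # --- volumetry on a 3D phantom scaled to the true volume trajectory
    volDays <- sort(unique(tr$day[tr$parameter == "volume_pct"]))
    baseVol <- config$cohort$baselineVolume
    absVols <- vapply(volDays, function(dy) {
      pct <- tr$value[tr$parameter == "volume_pct" & tr$day == dy]
      ph <- buildPhantom(dim = config$volumetryDim,
                         voxelSize = config$volumetryVoxel,
                         sliceThickness = config$volumetrySliceThickness,
                         targetVolume = baseVol * pct / 100,
                         nVessels = 0L, seed = .subSeed(config$seed, ai))
      liverVolume(liverMask(ph), voxArea, config$volumetrySliceThickness)
    }, numeric(1))
    rv <- relativeVolume(absVols, volDays, animalId = id)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = id, group = tr$group[1], day = rv$day,
      parameter = "volume_pct", value = rv$relative_pct, units = "percent")

    # --- parametric maps, one phantom slice per day
    for (dy in days) {
      vals <- tr$value[tr$day == dy]
      names(vals) <- tr$parameter[tr$day == dy]
      need <- intersect(c("T1", "T2", "ADC", "MTR"), names(vals))
      if (!length(need)) next
      tis <- .truthToTissue(c(
        T1 = unname(vals["T1"]), T2 = unname(vals["T2"]),
        ADC = unname(vals["ADC"]), MTR = unname(vals["MTR"])))
      ph <- buildPhantom(dim = config$phantomDim,
                         nVessels = config$nVessels,
                         vesselRadius = config$vesselRadius,
                         parenchyma = tis, seed = .subSeed(config$seed, ai))
      rois <- autoPlaceRois(ph, n = config$nRois, radius = config$roiRadius)
      paramOf <- c(ir_truefisp = "T1", multi_echo = "T2",
                   dwi = "ADC", mt_flash = "MTR")
      contrasts <- config$contrasts[paramOf[config$contrasts] %in% need]
      meas <- .measureMaps(ph, rois, contrasts, sigma,
                           seed = .subSeed(config$seed, ai * 1000 + dy))
      for (p in names(meas))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = tr$group[1], day = dy, parameter = p,
          value = meas[[p]],
          units = switch(p, T1 = , T2 = "ms", ADC = "1e-3 mm^2/s",
                         MTR = "percent"))
    }
  }
  measured <- do.call(rbind, rows)
  rownames(measured) <- NULL
  summary <- groupSummary(measured)

  statsOut <- list(
    anova = lapply(stats::setNames(nm = c("T1", "T2", "ADC", "MTR")),
                   function(p) twoWayAnovaBonferroni(measured, p)),
    correlation = lapply(stats::setNames(nm = c("cPH", "ePH")), function(g)
      pearsonVolumeCorrelation(measured, g, "T1")),
    plf_logit = tryCatch(plfLogisticRegression(measured, day = 1),
                         warning = function(w)
                           suppressWarnings(plfLogisticRegression(measured,
                                                                  day = 1)),
                         error = function(e) list(error = conditionMessage(e)))
  )

  manifest <- list(
    seed = config$seed, snr = config$snr,
    contrasts = config$contrasts,
    n_animals = length(animals),
    n_records_truth = nrow(truth),
    n_records_measured = nrow(measured),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      truth = file.path(config$outputDir, "cohort_truth.csv"),
      measured = file.path(config$outputDir, "cohort_measured.csv"),
      summary = file.path(config$outputDir, "group_summary.csv"))
    utils::write.csv(truth, paths["truth"], row.names = FALSE)
    utils::write.csv(measured, paths["measured"], row.names = FALSE)
    utils::write.csv(summary, paths["summary"], row.names = FALSE)
    manifest$outputs <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(truth = truth, measured = measured, summary = summary,
       stats = statsOut, manifest = manifest)
}
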