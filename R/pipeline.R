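#' @include synth-field.R synth-spikes.R modal.R encoding.R infomap.R localization.R io.R
NULL

#' Default pipeline configuration
#'
#' Every consumed parameter has a default here; user configs are merged over
#' these.  Units are mm, s, Hz and bits throughout.
#'
#' @return nested named list of stage parameters.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    fs = 1000,
    duration = 10,
    scenario = "flutter",                  # or "localization"
    stages = c("synth", "modes", "encode", "infomap"),
    synth = list(rows = 12L, cols = 20L, span = 40, chord = 10,
                 modes = c("bend", "twist", "camber"),
                 frequencies = c(170, 170, 340), rms = c(1.8, 1.1, 0.4),
                 harmonicWeights = c(0, 0, 0), amDepth = 0.6, amRateHz = 3,
                 noiseSD = 0.05, noiseRelative = TRUE,
                 nSensors = 30L, proximalFraction = 0.7),
    modes = list(n = 3L),
    encode = list(drivingMode = "bend", mu0 = 0.25, kappa = 4, p = 0.9,
                  beta = 0.02, refractory = 0.001, halfWindowMs = 25,
                  ampBins = seq(1, 4, length.out = 5)),
    infomap = list(segmentMs = 100, overlap = 0.5, band = c(0, 500),
                   percentile = 5, fieldKind = "strain"))
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (by extension), merges over [defaultRunConfig()] and
#' validates before anything runs.
#'
#' @param config path to a YAML/JSON config, or a named list (possibly
#'   partial).
#' @return validated config list.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- mergeConfig(defaultRunConfig(), config)
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$fs) || !is.numeric(cfg$fs) || cfg$fs <= 0)
    stop("config error: fs must be a positive number")
  if (is.null(cfg$duration) || cfg$duration <= 0)
    stop("config error: duration must be > 0")
  if (!cfg$scenario %in% c("flutter", "localization"))
    stop("config error: scenario must be 'flutter' or 'localization'")
  if (!all(cfg$stages %in% c("synth", "modes", "encode", "infomap")))
    stop("config error: unknown stage")
  if (any(cfg$synth$frequencies >= cfg$fs / 2))
    stop("config error: mode frequency at or above Nyquist")
  if (cfg$infomap$band[2] > cfg$fs / 2)
    stop("config error: coherence band exceeds Nyquist")
  invisible(TRUE)
}

## Stable JSON serialization used for both the report and its hash.
reportJSON <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, pretty = TRUE,
                   na = "null")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order synth -> modes -> encode ->
#' infomap on a synthetic scenario, writes all artifacts (field container,
#' spikes, sensors, per-stage CSVs) plus a machine-readable `report.json`
#' into `outputDir`, and returns the report.  The report carries the config
#' hash, package version and per-stage seeds; identical config and seed give
#' a byte-identical report.
#'
#' @param config config list or path (see [runConfig()]).
#' @param outputDir output directory (created).
#' @return the report, invisibly (a named list; also written as JSON).
#' @export
runPipeline <- function(config = list(), outputDir = tempfile("aeronerve_run_")) {
  cfg <- runConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  cfgJSON <- reportJSON(cfg)
  tmp <- tempfile(); writeLines(cfgJSON, tmp)
  cfgHash <- unname(tools::md5sum(tmp)); unlink(tmp)
  seeds <- list(synth = childSeed(cfg$seed, "synth"),
                encode = childSeed(cfg$seed, "encode"))
  report <- list(package = "aeronerve",
                 version = as.character(utils::packageVersion("aeronerve")),
                 configHash = cfgHash, seed = cfg$seed, stageSeeds = seeds)

  ## --- synth -------------------------------------------------------------
  if (cfg$scenario == "localization") {
    sc <- synthLocalizationScenario(seed = seeds$synth,
                                    duration = cfg$duration, fs = cfg$fs,
                                    grid = wingGrid(cfg$synth$rows,
                                                    cfg$synth$cols,
                                                    cfg$synth$span,
                                                    cfg$synth$chord))
    field <- sc$field; strain <- sc$strain; spikes <- sc$spikes
    sensors <- sc$sensors
    report$trueBin <- sc$trueBin
  } else {
    grid <- wingGrid(cfg$synth$rows, cfg$synth$cols, cfg$synth$span,
                     cfg$synth$chord)
    model <- modalModel(modes = cfg$synth$modes,
                        frequencies = cfg$synth$frequencies,
                        rms = cfg$synth$rms,
                        harmonicWeights = cfg$synth$harmonicWeights,
                        amDepth = cfg$synth$amDepth,
                        amRateHz = cfg$synth$amRateHz,
                        noiseSD = cfg$synth$noiseSD,
                        noiseRelative = cfg$synth$noiseRelative,
                        seed = seeds$synth)
    field <- synthDisplacementField(grid, model, cfg$duration, cfg$fs)
    strain <- synthStrainField(field)
    spikes <- synthSpikeTrain(groundTruth(field)$scores,
                              drivingMode = cfg$encode$drivingMode,
                              model = spikeModel(mu0 = cfg$encode$mu0,
                                                 kappa = cfg$encode$kappa,
                                                 p = cfg$encode$p,
                                                 beta = cfg$encode$beta,
                                                 refractory = cfg$encode$refractory,
                                                 seed = seeds$encode),
                              fs = cfg$fs)
    sensors <- synthSensorMap(grid, cfg$synth$nSensors,
                              cfg$synth$proximalFraction,
                              seed = seeds$synth + 1L)
  }
  if ("synth" %in% cfg$stages) {
    writeFieldContainer(field, file.path(outputDir, "field"))
    writeSpikes(spikes, file.path(outputDir, "spikes.csv"))
    writeSensorMap(sensors, file.path(outputDir, "sensors.csv"))
  }
  report$nFrames <- nFrames(field)
  report$nSpikes <- length(spikeTimes(spikes))

  ## --- modes -------------------------------------------------------------
  dec <- NULL
  if ("modes" %in% cfg$stages) {
    dec <- fitModes(field, cfg$modes$n)
    report$varianceFractions <- as.numeric(varianceFractions(dec))
    report$summedVariance <- sum(varianceFractions(dec))
    data.table::fwrite(data.table::as.data.table(modeScores(dec)),
                       file.path(outputDir, "scores.csv"))
  }

  ## --- encode ------------------------------------------------------------
  if ("encode" %in% cfg$stages) {
    if (is.null(dec)) stop("stage 'encode' needs stage 'modes' upstream")
    sc <- modeScores(dec)
    vsTab <- do.call(rbind, lapply(seq_len(ncol(sc)), function(j)
      phaseLocking(sc[, j], spikes, mode = paste0("PC", j))))
    report$vectorStrength <- vsTab[, c("mode", "n", "vs", "class", "meanPhase")]
    ## STA only for phase-locked units
    if (any(vsTab$class != "none")) {
      j <- which.max(vsTab$vs)
      sta <- spikeTriggeredAverage(sc, spikeFrames(spikes), cfg$fs,
                                   cfg$encode$halfWindowMs)
      data.table::fwrite(data.table::data.table(lag_ms = sta$lag_ms, sta$sta),
                         file.path(outputDir, "sta.csv"))
      report$sta <- list(mode = vsTab$mode[j], nSpikes = sta$nSpikes,
                         peakAbs = max(abs(sta$sta[, j])))
    }
  }

  ## --- infomap -----------------------------------------------------------
  if ("infomap" %in% cfg$stages) {
    yfield <- if (cfg$infomap$fieldKind == "strain") strain else field
    cm <- coherenceMap(spikes, yfield, segmentMs = cfg$infomap$segmentMs,
                       overlap = cfg$infomap$overlap, band = cfg$infomap$band)
    im <- highInformationRegions(cm, spikes,
                                 percentile = cfg$infomap$percentile,
                                 band = cfg$infomap$band)
    cand <- matchCandidateSensors(im, sensors)
    data.table::fwrite(cand, file.path(outputDir, "candidates.csv"))
    report$infomap <- list(
      fieldKind = cfg$infomap$fieldKind,
      nSegments = cm@nSegments,
      peakCoherence = max(cm@peakCoherence),
      peakFrequency = cm@peakFrequency[which.max(cm@peakCoherence)],
      maxBitsPerS = max(infoRate(im)),
      maxBitsPerSpike = max(infoRatePerSpike(im)),
      regionBins = sum(highInfoMask(im)),
      topCandidate = if (any(cand$in_region)) cand$sensor_id[which(cand$rank == 1)]
                     else NA_character_)
  }

  writeLines(reportJSON(report), file.path(outputDir, "report.json"))
  invisible(report)
}
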