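## Experiment driver: configuration, protocol chaining, serialization.

#' Run configuration
#'
#' @param network fixture name (see [fixtureNetwork()]) or a list
#'   `list(net = <Network>, neuron = <NeuronAddress>)`.
#' @param protocols any of `"rf_map"`, `"orientation"`, `"visualize"`,
#'   `"texture"` (rf_map always runs first when any other protocol is
#'   requested, since they need the optimal grating and GSF).
#' @param channels channels whose map-center units are probed.
#' @param layer layer to probe; `NULL` uses the fixture's canonical
#'   neuron's layer.
#' @param seed root seed; per-(neuron, protocol) streams are derived
#'   from it so results do not depend on batch composition.
#' @param grid optional grating search grid (see [defaultGratingGrid()]);
#'   `NULL` uses the protocol default.
#' @param vis visualization settings as from [visConfig()].
#' @param outdir output directory.
#' @return validated config list.
#' @export
runConfig <- function(network = "gabor_cs", protocols = "rf_map",
                      channels = 1L, layer = NULL, seed = 1L,
                      grid = NULL,
                      vis = visConfig(iterations = 100L),
                      outdir = tempfile("surroundscope_run_")) {
  bad <- setdiff(protocols, c("rf_map", "orientation", "visualize",
                              "texture"))
  if (length(bad)) stop("unknown protocols: ", paste(bad, collapse = ", "))
  list(network = network, protocols = protocols, channels = channels,
       layer = layer, seed = as.integer(seed), grid = grid, vis = vis,
       outdir = outdir)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file.
#' @return config list via [runConfig()].
#' @export
readRunConfig <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  vis <- do.call(visConfig, obj$vis %||% list())
  runConfig(network = obj$network %||% "gabor_cs",
            protocols = unlist(obj$protocols %||% "rf_map"),
            channels = unlist(obj$channels %||% 1L),
            layer = obj$layer %||% NULL,
            seed = obj$seed %||% 1L, vis = vis,
            outdir = obj$outdir %||% tempfile("surroundscope_run_"))
}

#' Run an experiment bundle
#'
#' Executes the requested protocols for each probed neuron and writes a
#' flat, diff-able result bundle: `config.json` (resolved config
#' snapshot), `neurons.csv` (one row per neuron), `curves/*.json`
#' (tuning curve bundles), `vis/*.png` (visualization images) and
#' `run.log`. Per-neuron failures are logged and skipped, never aborting
#' the batch. Reruns with the same config produce identical tables on
#' fixture networks.
#'
#' @param config from [runConfig()] or [readRunConfig()].
#' @return invisibly, the per-neuron records.
#' @export
runExperiment <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outdir, "curves"), showWarnings = FALSE)
  dir.create(file.path(config$outdir, "vis"), showWarnings = FALSE)
  logFile <- file.path(config$outdir, "run.log")
  logMsg <- function(...) cat(sprintf("[%s] %s\n",
    format(Sys.time(), "%H:%M:%S"), sprintf(...)), file = logFile,
    append = TRUE)
  snap <- config
  snap$vis$learningRateTable <- as.list(snap$vis$learningRateTable)
  if (!is.character(snap$network)) snap$network <- "in-memory network"
  writeLines(jsonlite::toJSON(snap, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(config$outdir, "config.json"))
  fx <- if (is.character(config$network)) fixtureNetwork(config$network)
        else config$network
  net <- fx$net
  layer <- config$layer %||% fx$neuron@layer
  rows <- list(); records <- list()
  if (length(config$protocols) == 0L) {
    logMsg("no protocols requested; config snapshot written")
    return(invisible(records))
  }
  for (ch in config$channels) {
    id <- sprintf("%s_ch%d", layer, ch)
    t0 <- proc.time()[3]
    rec <- tryCatch({
      r <- list()
      if (length(config$protocols)) {
        r <- mapReceptiveField(net, layer, channel = ch,
                               grid = config$grid)
        logMsg("%s rf_map done (%.1fs)", id, proc.time()[3] - t0)
      }
      if ("orientation" %in% config$protocols && !r$silent &&
          is.finite(r$gsf)) {
        tri <- orientationTriplet(net, r$neuron, r$optimal, r$geometry,
                                  r$gsf)
        r$triplet <- tri
        r$tuningCorrelation <- tuningCurveCorrelation(tri$center,
                                                      tri$suppression)
        r$circularVariance <- circularVariance(tri$center)
        r$orientationDeviation <- orientationDeviation(
          tri$suppression, r$optimal$orientation)
        sel <- selectNeuron(r$geometry, r$gsf, tri$center, tri$suppression)
        r$included <- sel$included
        writeLines(jsonlite::toJSON(list(
          orientations = tri$center@values,
          center = tri$center@responses,
          surround = tri$surround@responses,
          suppression = tri$suppression@responses), digits = NA),
          file.path(config$outdir, "curves", paste0(id, ".json")))
        logMsg("%s orientation done", id)
      }
      if ("visualize" %in% config$protocols && !r$silent &&
          is.finite(r$gsf)) {
        cfg <- config$vis
        cfg$seed <- config$seed + 17L * ch
        vr <- twoStepVisualize(net, r$neuron, r$geometry, r$gsf,
                               config = cfg)
        r$vis <- vr
        for (what in c("center", "suppressive", "facilitative"))
          writeImage(slot(vr, what),
                     file.path(config$outdir, "vis",
                               sprintf("%s_%s.png", id, what)))
        logMsg("%s visualize done", id)
      }
      if ("texture" %in% config$protocols && !r$silent) {
        sources <- lapply(1:4, function(i)
          generateProceduralTexture(config$seed + i, size = 64L))
        fams <- buildTextureFamilies(sources, nSeeds = 2L,
                                     seed = config$seed)
        r$texture <- textureProtocol(net, r$neuron, r$geometry, fams)
        logMsg("%s texture done", id)
      }
      r
    }, error = function(e) {
      logMsg("%s FAILED: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    records[[id]] <- rec
    rows[[id]] <- data.frame(
      id = id, layer = layer, channel = ch,
      orientation = rec$optimal$orientation %||% NA,
      period = rec$optimal$period %||% NA,
      gsf = rec$gsf %||% NA, si = rec$si %||% NA,
      silent = isTRUE(rec$silent),
      included = rec$included %||% NA,
      tuningCorrelation = rec$tuningCorrelation %||% NA,
      circularVariance = rec$circularVariance %||% NA,
      orientationDeviation = rec$orientationDeviation %||% NA,
      siTexture = rec$texture$siTexture %||% NA,
      siNoise = rec$texture$siNoise %||% NA)
  }
  if (length(rows))
    utils::write.csv(do.call(rbind, rows),
                     file.path(config$outdir, "neurons.csv"),
                     row.names = FALSE)
  logMsg("run complete: %d neurons", length(records))
  invisible(records)
}

#' Layer-level population summary
#'
#' Means and standard errors of the per-neuron metrics in a result
#' bundle, per layer, written as tidy CSV next to the bundle.
#'
#' @param outdir result bundle directory (containing `neurons.csv`).
#' @return summary data.frame (invisibly written to
#'   `summary/summary.csv`).
#' @export
summarizePopulation <- function(outdir) {
  path <- file.path(outdir, "neurons.csv")
  if (!file.exists(path)) stop("no neurons.csv in ", outdir)
  df <- utils::read.csv(path)
  dir.create(file.path(outdir, "summary"), showWarnings = FALSE)
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  metrics <- c("gsf", "si", "tuningCorrelation", "circularVariance",
               "orientationDeviation", "siTexture", "siNoise")
  out <- do.call(rbind, lapply(split(df, df$layer), function(sub) {
    row <- data.frame(layer = sub$layer[1], n = nrow(sub))
    for (m in metrics) {
      v <- suppressWarnings(as.numeric(sub[[m]]))
      row[[paste0(m, "_mean")]] <- if (any(is.finite(v)))
        mean(v[is.finite(v)]) else NA_real_
      row[[paste0(m, "_sem")]] <- sem(v)
    }
    row
  }))
  utils::write.csv(out, file.path(outdir, "summary", "summary.csv"),
                   row.names = FALSE)
  invisible(out)
}
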