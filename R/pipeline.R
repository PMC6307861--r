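#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks whose defaults mirror the
#' analysis settings used throughout the package (displacement fitting
#' with 8 timepoints / 4 jumps / 1 gap over a 0.8 um detection slice; 1e-3
#' survival-probability cut; 85th-percentile hub threshold; 2.18 um locus
#' windows with a 2.6 um control offset; 24 ms FRAP frames), plus the RNG
#' seed every stochastic stage derives its stream from.
#'
#' @return named list (class \code{PipelineConfig}).
#' @export
defaultConfig <- function() {
  cfg <- list(
    rng_seed = 1L,
    io = list(pixel_size_xy = 0.1, out_dir = "smtf-out"),
    simulate = list(preset = "zld_like", n_molecules = 10000L,
                    frame_interval = 0.01, exposure = 0.01, n_frames = 30L,
                    slice_depth = 0.8),
    track = list(movie = NULL, sigma_psf = 1.3, threshold_mads = 6,
                 max_disp = 0.5, max_gap = 1L, frame_interval = 0.01),
    kinetics = list(tracks = NULL, timepoints = 8L, jumps_per_traj = 4L,
                    gaps_allowed = 1L, slice_depth = 0.8, n_init = 5L),
    residence = list(tracks = NULL, control_tracks = NULL,
                     min_prob_cut = 1e-3, threshold_candidates = "1:8"),
    msd = list(tracks = NULL, max_lag_fraction = 0.25),
    hubs = list(image = NULL, tracks = NULL, threshold_percentile = 85,
                sigma = 5, sensitivity = 0.6, dilation_radius = 3,
                area_range = c(1000, 20000), ecc_max = 0.9),
    locus = list(mcp = NULL, tf = NULL, nucleus_mask = NULL, nz = 25L,
                 voxel_size_z = 0.25, dog_sigmas = c(1.3, 3.9),
                 det_threshold = 8, min_contrast = 2, max_disp = 1,
                 window_um = 2.18, control_offset_um = 2.6, z_half_um = 2.5),
    frap = list(traces = NULL, subtract_dark_from_control = TRUE,
                outlier_factor = 3)
  )
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return \code{readConfig}: the configuration list merged over the
#'   defaults.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("missing config: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultConfig(), user)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' @rdname readConfig
#' @param config a configuration list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Polynomial rolling hash of the YAML serialization; identifies the
# configuration in reports.
configHash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stageReport <- function(config, stage, result, outDir) {
  rep <- list(stage = stage, config_hash = configHash(config),
              rng_seed = config$rng_seed,
              package_version = as.character(utils::packageVersion("smtf")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              result = result)
  path <- file.path(outDir, paste0(stage, "-report.json"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rep
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (trajectory generator), \code{track} (spot
#' detection + linking on a movie), \code{kinetics} (two-state
#' displacement fit), \code{residence} (survival-probability residence
#' time with bias control), \code{msd} (TAMSD + anomalous exponent),
#' \code{hubs} (segmentation, density map, enrichment), \code{locus}
#' (MS2 detection, tracking, radial profiles), \code{frap} (bleach
#' correction + reaction-dominant fit). Stage outputs are written to the
#' configured output directory together with a JSON report embedding the
#' configuration hash and seed, so identical configurations reproduce
#' stochastic outputs bit-identically.
#'
#' @param config a \code{\link{defaultConfig}}-style list.
#' @param stage stage name.
#' @param outDir output directory (created if needed); defaults to the
#'   configured one.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config, stage, outDir = NULL) {
  stages <- c("simulate", "track", "kinetics", "residence", "msd", "hubs",
              "locus", "frap")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  outDir <- outDir %||% config$io$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  need <- function(x, what) {
    if (is.null(x)) stop("missing input: ", what)
    x
  }
  res <- switch(stage,
    simulate = {
      s <- config$simulate
      p <- kineticPreset(s$preset, nMolecules = s$n_molecules,
                         frameInterval = s$frame_interval,
                         exposure = s$exposure, nFrames = s$n_frames,
                         sliceDepth = s$slice_depth,
                         seed = config$rng_seed)
      sim <- simulateTrajectories(p)
      writeTracks(sim$tracks, file.path(outDir, "trajectories.csv"))
      utils::write.csv(sim$truth, file.path(outDir, "ground-truth.csv"),
                       row.names = FALSE)
      list(n_trajectories = nTracks(sim$tracks),
           trajectories = file.path(outDir, "trajectories.csv"),
           ground_truth = file.path(outDir, "ground-truth.csv"))
    },
    track = {
      s <- config$track
      mov <- readMovie(need(s$movie, "track movie"),
                       list(pixelSizeXY = config$io$pixel_size_xy,
                            frameInterval = s$frame_interval))
      locs <- lapply(frames(mov), detectSpots, sigmaPsf = s$sigma_psf,
                     thresholdMads = s$threshold_mads,
                     pixelSizeXY = pixelSizeXY(mov))
      tracks <- linkTrajectories(locs, maxDisp = s$max_disp,
                                 maxGap = s$max_gap,
                                 frameInterval = s$frame_interval)
      writeTracks(tracks, file.path(outDir, "tracked.csv"))
      list(n_trajectories = nTracks(tracks),
           tracks = file.path(outDir, "tracked.csv"))
    },
    kinetics = {
      s <- config$kinetics
      tracks <- readTracks(need(s$tracks, "kinetics tracks"))
      ds <- compileDisplacements(tracks, timepoints = s$timepoints,
                                 jumpsPerTraj = s$jumps_per_traj,
                                 gapsAllowed = s$gaps_allowed)
      fit <- fitTwoState(ds, sliceDepth = s$slice_depth, nInit = s$n_init)
      list(f_bound = fit@fBound, d_bound = fit@dBound, d_free = fit@dFree,
           sigma_loc = fit@sigmaLoc, loss = fit@loss)
    },
    residence = {
      s <- config$residence
      tracks <- readTracks(need(s$tracks, "residence tracks"))
      ctrl <- readTracks(need(s$control_tracks, "residence control tracks"))
      sp <- survivalProbability(tracks)
      csp <- survivalProbability(ctrl)
      cand <- eval(parse(text = s$threshold_candidates))
      thr <- suppressWarnings(
        selectMinDurationThreshold(sp, cand, s$min_prob_cut))
      fit <- fitDoubleExponential(sp, thr, s$min_prob_cut)
      cthr <- suppressWarnings(
        selectMinDurationThreshold(csp, cand, s$min_prob_cut))
      cfit <- fitDoubleExponential(csp, cthr, s$min_prob_cut)
      est <- biasCorrectResidenceTime(fit, cfit)
      list(k_s = est@kS, k_bias = est@kBias, k_s_true = est@kSTrue,
           tau_res = est@tauRes, min_duration_frames = as.integer(thr))
    },
    msd = {
      s <- config$msd
      tracks <- readTracks(need(s$tracks, "msd tracks"))
      curve <- computeTamsd(tracks, maxLagFraction = s$max_lag_fraction)
      utils::write.csv(data.frame(lag = curve@lag, msd = curve@msd,
                                  n_pairs = curve@nPairs),
                       file.path(outDir, "tamsd.csv"), row.names = FALSE)
      fit <- fitAnomalous(curve)
      list(alpha = fit@alpha, gamma = fit@gamma,
           curve = file.path(outDir, "tamsd.csv"))
    },
    hubs = {
      s <- config$hubs
      mov <- readMovie(need(s$image, "hubs image"),
                       list(pixelSizeXY = config$io$pixel_size_xy,
                            frameInterval = 1))
      tracks <- readTracks(need(s$tracks, "hubs tracks"))
      seg <- segmentNuclei(frames(mov)[[1]], sigma = s$sigma,
                           sensitivity = s$sensitivity,
                           dilationRadius = s$dilation_radius,
                           areaRange = s$area_range, eccMax = s$ecc_max)
      map <- relativeDensityMap(frames(mov)[[1]], seg,
                                pixelSizeXY = pixelSizeXY(mov))
      er <- foldEnrichment(tracks, map, threshold = s$threshold_percentile)
      list(n_nuclei = length(seg@area), fold_enrichment = er@foldEnrichment,
           count_in = er@countIn, count_out = er@countOut,
           area_in = er@areaIn, area_out = er@areaOut)
    },
    locus = {
      s <- config$locus
      meta <- list(pixelSizeXY = config$io$pixel_size_xy,
                   frameInterval = 5, nz = s$nz,
                   voxelSizeZ = s$voxel_size_z)
      mcp <- readMovie(need(s$mcp, "locus MCP channel"), meta)
      tf <- readMovie(need(s$tf, "locus TF channel"), meta)
      maskMov <- readMovie(need(s$nucleus_mask, "locus nucleus mask"),
                           list(pixelSizeXY = config$io$pixel_size_xy,
                                frameInterval = 1))
      mask <- frames(maskMov)[[1]] > 0.5
      dets <- list()
      for (t in seq_along(frames(mcp))) {
        vol <- frames(mcp)[[t]]
        dd <- detectLoci(vol, dogSigmas = s$dog_sigmas,
                         threshold = s$det_threshold,
                         pixelSizeXY = pixelSizeXY(mcp),
                         voxelSizeZ = s$voxel_size_z)
        if (nrow(dd)) {
          dd <- do.call(rbind, lapply(seq_len(nrow(dd)), function(i)
            contrastFilter(dd[i, ], vol, minRatio = s$min_contrast,
                           pixelSizeXY = pixelSizeXY(mcp),
                           voxelSizeZ = s$voxel_size_z)))
          dd <- dd[dd$keep, , drop = FALSE]
          if (nrow(dd)) {
            dd$timepoint <- t
            dets[[length(dets) + 1L]] <- dd
          }
        }
      }
      if (!length(dets)) stop("no loci detected")
      dets <- trackLoci(do.call(rbind, dets), maxDisp = s$max_disp)
      wins <- cropWindows(dets, tf, mask, windowUm = s$window_um,
                          controlOffsetUm = s$control_offset_um,
                          zHalfUm = s$z_half_um)
      if (!dim(wins$ts)[3]) stop("no valid locus windows")
      tsProf <- averageAndRadialProfile(wins$ts, config$io$pixel_size_xy)
      rsProf <- averageAndRadialProfile(wins$rs, config$io$pixel_size_xy)
      utils::write.csv(
        data.frame(radius = tsProf$profile@radius,
                   ts = tsProf$profile@meanIntensity,
                   ts_se = tsProf$profile@se,
                   rs = rsProf$profile@meanIntensity,
                   rs_se = rsProf$profile@se),
        file.path(outDir, "radial-profiles.csv"), row.names = FALSE)
      list(n_windows = dim(wins$ts)[3],
           central_enrichment = tsProf$profile@meanIntensity[1],
           profiles = file.path(outDir, "radial-profiles.csv"))
    },
    frap = {
      s <- config$frap
      exp <- readFrapTraces(need(s$traces, "frap traces"))
      cc <- bleachCorrect(exp,
                          subtractDarkFromControl = s$subtract_dark_from_control,
                          outlierFactor = s$outlier_factor)
      fit <- fitReactionDominant(cc)
      list(a_amp = fit@aAmp, b_amp = fit@bAmp, k_a = fit@kA, k_b = fit@kB,
           t_half_slow = fit@tHalfSlow, n_spots_used = cc$nSpotsUsed)
    })
  invisible(stageReport(config, stage, res, outDir))
}
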