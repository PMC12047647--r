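# workflow_cli: config-driven orchestration of the full chain
# phantom -> conductivity -> EM basis -> (TI planning | tACS drive) ->
# network simulation -> virtual EEG -> DFC, with per-stage seeds and a
# provenance manifest.

.stageNames <- c("phantom", "conductivity", "em", "ti", "network", "eeg", "dfc")

# counter-based per-stage seed derivation (stays below 2^31)
.stageSeed <- function(master, stage) {
  idx <- match(stage, .stageNames)
  as.integer((as.numeric(master) * 1009 + idx * 7919) %% 2147483647)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: the five-shell sphere phantom (92/86/80/78/70 mm,
#' scalp/skull/CSF/GM/WM at 0.4/0.01/1.8/0.3/0.15 S/m) at 2 mm spacing, a
#' 21-electrode 10-10 subset (10-20 set plus AF7/AF8) referenced at Cz,
#' an 84-region bi-hemispheric connectome, a 642-vertex cortical mesh,
#' and a 31 s region-mode baseline simulation (1 s burn-in).
#'
#' @param ... top-level overrides (partial lists are merged).
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(phantom = TRUE, conductivity = TRUE, em = TRUE,
                  ti = FALSE, network = TRUE, eeg = TRUE, dfc = TRUE),
    phantom = list(radii = c(92, 86, 80, 78, 70),
                   conductivities = c(0.4, 0.01, 1.8, 0.3, 0.15),
                   spacing = 2, nVertices = 642, nRegions = 84L,
                   decayMm = 40, interhemisphericScale = 0.5),
    conductivity = list(anisotropic = FALSE, mode = "linear_scaling",
                        k = 844, sigmaCap = 2, c = 3),
    em = list(electrodes = c("Fp1", "Fp2", "AF7", "AF8", "F7", "F3", "Fz",
                             "F4", "F8", "T7", "C3", "Cz", "C4", "T8",
                             "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
              reference = "Cz", tol = 1e-8),
    ti = list(candidates = c("F3", "F4", "P3", "P4"), totalCurrent = 2,
              ratios = seq(0.1, 0.9, by = 0.1), weights = c(1, 1, 1),
              freqs = c(2000, 2070), targetRadius = 15,
              targetCenter = c(0, 0, 40), p = 50),
    network = list(mode = "region", duration = 31, dt = 5e-4, burnin = 1,
                   recordEvery = 1L, params = list()),
    eeg = list(windowSec = 2, overlap = 0.5, sourceScale = 1),
    dfc = list(windowSec = 10, overlap = 0.5, k = 3L, nInit = 10L)
  )
  ov <- list(...)
  .mergeConfig(cfg, ov)
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at every level against the schema of
#' [defaultPipelineConfig()].
#'
#' @param config nested list (e.g. parsed from YAML).
#' @return the config, invisibly, or an error naming the offending key.
#' @export
validatePipelineConfig <- function(config) {
  ref <- defaultPipelineConfig()
  check <- function(cfg, refcfg, path) {
    unknown <- setdiff(names(cfg), names(refcfg))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    for (nm in names(cfg))
      if (is.list(refcfg[[nm]]) && !is.null(names(refcfg[[nm]])) &&
          nm != "params" && is.list(cfg[[nm]]))
        check(cfg[[nm]], refcfg[[nm]], paste0(path, nm, "$"))
  }
  check(config, ref, "")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated config merged over the defaults.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  validatePipelineConfig(user)
  defaultPipelineConfig() |> .mergeConfig(user)
}

# Build the shared upstream artifacts (phantom ... lead field).
.pipelinePrepare <- function(config, verbose = FALSE) {
  pc <- config$phantom
  say <- function(...) if (verbose) message(sprintf(...))
  say("[phantom] building sphere phantom (spacing %g mm)", pc$spacing)
  phantom <- buildSpherePhantom(pc$radii, pc$conductivities, pc$spacing,
                                seed = .stageSeed(config$seed, "phantom"))
  montage <- placeElectrodes1010(phantom)
  montage@reference <- config$em$reference
  mesh <- tessellateCortex(phantom, nVertices = pc$nVertices,
                           nRegions = pc$nRegions)
  gm <- .shellRadii(phantom, "gm")
  connectome <- synthConnectome(pc$nRegions, decayMm = pc$decayMm,
                                interhemisphericScale = pc$interhemisphericScale,
                                seed = .stageSeed(config$seed, "phantom"),
                                radiusMm = mean(gm))
  cc <- config$conductivity
  wmT <- NULL
  if (isTRUE(cc$anisotropic)) {
    say("[conductivity] anisotropic WM tensors (%s)", cc$mode)
    dti <- synthFiberTensors(phantom,
                             seed = .stageSeed(config$seed, "conductivity"))
    wmT <- dtiToConductivity(dti, mode = cc$mode, k = cc$k,
                             sigmaCap = cc$sigmaCap, c = cc$c)
  }
  sigma <- assignTissueConductivity(phantom, wmT)
  say("[em] field basis for %d electrodes", length(config$em$electrodes))
  basis <- computeFieldBasis(sigma, phantom, montage,
                             labels = config$em$electrodes,
                             tol = config$em$tol, verbose = verbose)
  lf <- leadFieldReciprocity(basis, mesh)
  list(phantom = phantom, montage = montage, mesh = mesh,
       connectome = connectome, sigma = sigma, basis = basis, lf = lf)
}

.baselineNetwork <- function(config, prep) {
  nc <- config$network
  params <- do.call(jrParams, nc$params)
  buildNetworkModel(prep$connectome,
                    mesh = if (nc$mode == "surface") prep$mesh else NULL,
                    mode = nc$mode, params = params)
}

#' Run the configured pipeline end to end
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' artifacts under `outDir`, and returns (and writes) a manifest with
#' artifact hashes and the per-stage seeds. Reruns with the same config
#' reproduce the stochastic stages bit-exactly.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir output directory (created if missing).
#' @param verbose log stage progress.
#' @return list with the in-memory artifacts and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = tempdir(),
                        verbose = FALSE) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  artifacts <- character(0)
  out <- list(config = config)
  if (!isTRUE(st$phantom)) stop("the phantom stage cannot be disabled")
  prep <- .pipelinePrepare(config, verbose = verbose)
  out <- c(out, prep)
  writePhantom(prep$phantom, file.path(outDir, "phantom"))
  writeMontage(prep$montage, file.path(outDir, "montage.csv"))
  writeConnectome(prep$connectome, file.path(outDir, "connectome"))
  artifacts <- c(artifacts, file.path(outDir, c("phantom.nii.gz",
                                                "montage.csv",
                                                "connectome_weights.csv")))
  if (isTRUE(st$ti)) {
    tc <- config$ti
    target <- .ballMask(prep$phantom, tc$targetCenter, tc$targetRadius)
    brain <- .brainMask(prep$phantom)
    configs <- enumerateConfigs(tc$candidates, totalCurrent = tc$totalCurrent,
                                ratios = tc$ratios, freqs = tc$freqs)
    mets <- lapply(configs, function(cf)
      exposureMetrics(exposureMap(prep$basis, cf), target, brain, p = tc$p))
    ranked <- weightedRank(paretoFront(mets, configs), tc$weights)
    out$tiPlan <- ranked
    planPath <- file.path(outDir, "ti_plan.json")
    jsonlite::write_json(rankedConfigTable(ranked), planPath, digits = NA)
    artifacts <- c(artifacts, planPath)
  }
  if (isTRUE(st$network)) {
    nc <- config$network
    network <- .baselineNetwork(config, prep)
    out$network <- network
    sim <- simulateNetwork(network, do.call(jrParams, nc$params),
                           drive = NULL, duration = nc$duration, dt = nc$dt,
                           burnin = nc$burnin,
                           seed = .stageSeed(config$seed, "network"),
                           recordEvery = nc$recordEvery)
    out$sim <- sim
    if (isTRUE(st$eeg)) {
      lfUse <- if (nc$mode == "region")
        aggregateLeadField(prep$lf, prep$mesh) else prep$lf
      rec <- projectEEG(sim, lfUse, sourceScale = config$eeg$sourceScale)
      out$eeg <- rec
      eegPath <- file.path(outDir, "eeg.csv")
      writeEEG(rec, eegPath)
      artifacts <- c(artifacts, eegPath)
      out$psd <- psdWelch(rec, windowSec = config$eeg$windowSec,
                          overlap = config$eeg$overlap)
    }
    if (isTRUE(st$dfc)) {
      dc <- config$dfc
      dfc <- slidingFC(sim, windowSec = dc$windowSec, overlap = dc$overlap)
      states <- clusterStates(dfc, k = dc$k,
                              seed = .stageSeed(config$seed, "dfc"),
                              nInit = dc$nInit)
      states <- pcaProject(dfc, 2, states)
      out$dfc <- dfc
      out$states <- states
      dfcPath <- file.path(outDir, "dfc_states.csv")
      write.csv(data.frame(window = seq_along(states@stateLabels),
                           center = dfc@centers,
                           state = states@stateLabels), dfcPath,
                row.names = FALSE)
      artifacts <- c(artifacts, dfcPath)
    }
  }
  manifest <- list(
    seeds = setNames(lapply(.stageNames, .stageSeed, master = config$seed),
                     .stageNames),
    stages = st,
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           row.names = NULL)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  out
}

#' Brain and spherical target masks of a phantom
#'
#' `brainMask()` marks the GM + WM voxels; `targetBallMask()` marks the
#' brain voxels within `radius` mm of a world-coordinate `center` —
#' the usual way to define an optimization target on the phantom.
#'
#' @param phantom a [TissuePhantom-class].
#' @param center numeric(3) world coordinates, mm.
#' @param radius ball radius, mm.
#' @return logical array over the phantom grid.
#' @export
brainMask <- function(phantom) .brainMask(phantom)

#' @rdname brainMask
#' @export
targetBallMask <- function(phantom, center, radius)
  .ballMask(phantom, center, radius)

# ball mask in world coordinates, restricted to brain labels
.ballMask <- function(phantom, center, radius) {
  dims <- dim(phantom@labels)
  idx <- seq_len(prod(dims))
  ijk <- arrayInd(idx, dims) - 1L
  xyz <- sweep(sweep(ijk, 2, phantom@spacing, "*"), 2, phantom@origin, "+")
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  array(d2 <= radius^2, dims) & .brainMask(phantom)
}

# brain = GM + WM labels
.brainMask <- function(phantom) {
  tab <- phantom@tissueTable
  brainLabs <- tab$label[tab$name %in% c("gm", "wm")]
  array(as.integer(phantom@labels) %in% brainLabs, dim(phantom@labels))
}

#' tACS demonstration: spectral response to alternating-current drives
#'
#' Reproduces the package's tACS demonstration on the phantom: for each
#' stimulating montage and frequency, a surface-mode Jansen-Rit run with
#' the lambda*E drive applied during the central window is compared with
#' the identically seeded baseline run; the report collects the
#' frequency of the largest PSD increase, alpha-band topography, and
#' near- vs far-channel gains.
#'
#' @param config pipeline configuration.
#' @param prep optional pre-built artifact list from an earlier run
#'   (avoids re-solving the EM basis).
#' @param montages list of character(2) stimulating pairs.
#' @param freqs drive frequencies, Hz.
#' @param currentMa channel current, mA.
#' @param lambda membrane space constant for the demonstration, mm.
#' @param duration,stimWindow,burnin timing, s.
#' @param nearChannel,farChannel channels for the near/far comparison.
#' @param verbose log progress.
#' @return list(results = data.frame, psd = list, topo = list,
#'   spectrograms = list)
#' @export
demoTacs <- function(config = defaultPipelineConfig(), prep = NULL,
                     montages = list(c("P7", "P8"), c("P7", "AF7"),
                                     c("AF7", "AF8")),
                     freqs = c(8, 15), currentMa = 2, lambda = 5,
                     duration = 91, stimWindow = c(31, 61), burnin = 1,
                     nearChannel = "P7", farChannel = "AF7",
                     verbose = FALSE) {
  validatePipelineConfig(config)
  if (is.null(prep)) prep <- .pipelinePrepare(config, verbose = verbose)
  nc <- config$network
  params <- do.call(jrParams, nc$params)
  network <- buildNetworkModel(prep$connectome,
                               mesh = if (nc$mode == "surface") prep$mesh,
                               mode = nc$mode, params = params)
  lfUse <- if (nc$mode == "region") aggregateLeadField(prep$lf, prep$mesh)
           else prep$lf
  seed <- .stageSeed(config$seed, "network")
  base <- simulateNetwork(network, params, drive = NULL, duration = duration,
                          dt = nc$dt, burnin = burnin, seed = seed)
  baseEEG <- projectEEG(base, lfUse)
  stimSel <- function(rec) {
    tt <- burnin + seq_len(ncol(rec@data)) / rec@fs
    i <- which(tt >= stimWindow[1] & tt < stimWindow[2])
    new("EEGRecord", labels = rec@labels, fs = rec@fs,
        data = rec@data[, i, drop = FALSE], reference = rec@reference)
  }
  basePsd <- psdWelch(stimSel(baseEEG), config$eeg$windowSec,
                      config$eeg$overlap)
  rows <- list(); psds <- list(); topos <- list(); sgrams <- list()
  for (mp in montages) for (fq in freqs) {
    key <- sprintf("%s-%s@%gHz", mp[1], mp[2], fq)
    if (verbose) message("[demo] ", key)
    drv <- tacsDrive(prep$basis, mp, currentMa, network, lambda, fq,
                     window = stimWindow)
    sim <- simulateNetwork(network, params, drive = drv, duration = duration,
                           dt = nc$dt, burnin = burnin, seed = seed)
    rec <- projectEEG(sim, lfUse)
    sp <- psdWelch(stimSel(rec), config$eeg$windowSec, config$eeg$overlap)
    dpsd <- sp@channelMean - basePsd@channelMean
    sel <- which(sp@freq > 1)
    pk <- sp@freq[sel[which.max(dpsd[sel])]]
    band <- c(fq - 1, fq + 1)
    gain <- bandPowerFromPsd(sp, band) - bandPowerFromPsd(basePsd, band)
    rows[[key]] <- data.frame(
      montage = paste(mp, collapse = "-"), freqHz = fq,
      peakIncreaseHz = pk,
      nearGain = unname(gain[nearChannel]),
      farGain = unname(gain[farChannel]))
    psds[[key]] <- sp
    topos[[key]] <- bandPowerFromPsd(sp, c(8, 12)) -
      bandPowerFromPsd(basePsd, c(8, 12))
    sgrams[[key]] <- spectrogramEEG(rec, nearChannel,
                                    windowSec = config$eeg$windowSec,
                                    stepSec = 1)
  }
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       baselinePsd = basePsd, psd = psds, alphaTopo = topos,
       spectrograms = sgrams)
}
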