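# jr_network: Jansen-Rit whole-brain network simulation with delayed
# long-range coupling, Gaussian local coupling and lambda*E stimulation
# coupling.

#' Jansen-Rit model and network parameters
#'
#' Defaults are the standard parameterization of the model: excitatory /
#' inhibitory synaptic gains A = 3.25 mV and B = 22 mV, PSP rate
#' constants a = 100 1/s and b = 50 1/s, connectivity constants C1 = 135,
#' C2 = 0.8 C1, C3 = C4 = 0.25 C1, sigmoid parameters v0 = 5.52 mV,
#' e0 = 2.5 1/s, r = 0.56 1/mV. Network-level defaults: global coupling
#' G = 7, additive noise intensity 1e-7 (TVB-style, on the excitatory PSP
#' rate state), conduction speed 3 mm/ms, Gaussian local kernel
#' (width 10 mm, amplitude 1, cutoff 20 mm), effective membrane space
#' constant lambda = 1 mm, and mean background pulse density
#' pMean = 250 1/s (inside the model's alpha-expressing
#' oscillatory input range for the v0 = 5.52 mV sigmoid midpoint).
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
jrParams <- function(...) {
  p <- list(
    A = 3.25, B = 22, a = 100, b = 50,
    C1 = 135, C2 = 0.8 * 135, C3 = 0.25 * 135, C4 = 0.25 * 135,
    v0 = 5.52, e0 = 2.5, r = 0.56,
    G = 7, noiseSigma = 1e-7, pMean = 250,
    conductionSpeed = 3,                       # mm/ms
    localWidth = 10, localAmplitude = 1, localCutoff = 20,   # mm
    lambda = 1                                 # mm
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$A > 0, p$B > 0, p$a > 0, p$b > 0, p$e0 > 0, p$r > 0)
  p
}

#' Sigmoidal potential-to-rate transformation
#'
#' S(v) = 2 e0 / (1 + exp(r (v0 - v))): S(v0) = e0, saturating at 2 e0.
#'
#' @param v membrane potential, mV.
#' @param params parameter list from [jrParams()].
#' @return firing rate, 1/s.
#' @export
jrSigmoid <- function(v, params = jrParams()) {
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

#' Build a Jansen-Rit network model
#'
#' Region mode places one node per connectome region at its centroid
#' (radial normals); surface mode places one node per mesh vertex, maps
#' the region-level long-range weights to vertices, and adds a Gaussian
#' local coupling w_ij = amplitude * exp(-d_ij^2 / (2 width^2)) for
#' great-circle distances d_ij <= cutoff (zero diagonal).
#'
#' @param connectome a [Connectome-class].
#' @param mesh a [CorticalMesh-class] (required for surface mode).
#' @param mode "region" or "surface".
#' @param params parameter list from [jrParams()].
#' @return a [NetworkModel-class]
#' @export
buildNetworkModel <- function(connectome, mesh = NULL,
                              mode = c("region", "surface"),
                              params = jrParams()) {
  mode <- match.arg(mode)
  if (mode == "region") {
    pos <- connectome@centroids
    nrm <- pos / sqrt(rowSums(pos^2))
    new("NetworkModel", mode = mode, positions = pos, normals = nrm,
        region = seq_len(nrow(pos)), weights = connectome@weights,
        lengths = connectome@lengths, localW = NULL)
  } else {
    if (is.null(mesh)) stop("surface mode needs a mesh")
    if (mesh@nRegions != nrow(connectome@weights))
      stop("mesh and connectome disagree on the region count")
    pos <- mesh@vertices
    rad <- sqrt(rowSums(pos^2))
    R <- mean(rad)
    # great-circle distances on the (spherical) cortical surface
    cosang <- tcrossprod(pos / rad)
    cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
    d <- R * acos(cosang)
    w <- params$localAmplitude * exp(-d^2 / (2 * params$localWidth^2))
    w[d > params$localCutoff] <- 0
    diag(w) <- 0
    localW <- methods::as(
      methods::as(Matrix::Matrix(w, sparse = TRUE), "generalMatrix"),
      "CsparseMatrix")
    new("NetworkModel", mode = mode, positions = pos, normals = mesh@normals,
        region = mesh@region, weights = connectome@weights,
        lengths = connectome@lengths, localW = localW)
  }
}

#' Delay steps of the long-range connections at a given time step
#'
#' tau_ij = round(length_ij / speed / dt), in integration steps.
#'
#' @param network a [NetworkModel-class].
#' @param dt time step, s.
#' @param speed conduction speed, mm/ms.
#' @return integer matrix of delay steps (region level).
#' @export
delaySteps <- function(network, dt, speed = 3) {
  round(network@lengths / speed / (dt * 1000))
}

#' Build a stimulus drive from a field sampled at the network nodes
#'
#' Per-node amplitude lambda * (E . n) in mV (1 V/m x 1 mm = 1 mV); the
#' waveform (sinusoid, dc, or Hann-enveloped sinusoid) is applied inside
#' the on/off window.
#'
#' @param efield n x 3 matrix of field vectors at the node positions, V/m.
#' @param network a [NetworkModel-class] (provides normals).
#' @param lambda effective membrane space constant, mm.
#' @param freqHz waveform frequency, Hz.
#' @param window numeric(2) on/off times, s.
#' @param shape "sinusoid", "dc" or "am".
#' @return a [StimulusDrive-class]
#' @export
makeStimulusDrive <- function(efield, network, lambda = 1, freqHz = 10,
                              window = c(0, Inf),
                              shape = c("sinusoid", "dc", "am")) {
  shape <- match.arg(shape)
  if (nrow(efield) != nrow(network@normals))
    stop("field rows must match network nodes")
  amp <- lambda * rowSums(efield * network@normals)
  new("StimulusDrive", amplitude = amp, freqHz = freqHz,
      window = as.numeric(window), shape = shape)
}

#' Convenience: tACS drive from an E-field basis
#'
#' Interpolates the pair field (scaled by the channel current) at the
#' node positions and builds the sinusoidal drive.
#'
#' @param basis an [EFieldBasis-class].
#' @param pair character(2) stimulating electrode labels.
#' @param currentMa channel current, mA.
#' @param network a [NetworkModel-class].
#' @param lambda membrane space constant, mm.
#' @param freqHz stimulation frequency, Hz.
#' @param window on/off times, s.
#' @return a [StimulusDrive-class]
#' @export
tacsDrive <- function(basis, pair, currentMa, network, lambda, freqHz,
                      window) {
  field <- basisField(basis, pair[1], pair[2]) * currentMa
  Ev <- .interpField(field, basis@origin, basis@spacing, network@positions)
  makeStimulusDrive(Ev, network, lambda = lambda, freqHz = freqHz,
                    window = window, shape = "sinusoid")
}

#' Simulate the Jansen-Rit network
#'
#' Integrates the six-state Jansen-Rit system per node with a stochastic
#' Heun (predictor-corrector trapezoidal) scheme. Node input is the mean
#' background pulse density plus G-scaled delayed long-range firing-rate
#' coupling (region granularity), the local kernel term in surface mode,
#' and TVB-style additive noise of intensity `noiseSigma` on the
#' excitatory PSP rate state (per-step increment
#' sqrt(2 noiseSigma dt_ms) mV/ms, the same Wiener increment in predictor
#' and corrector). The stimulus lambda (E.n) waveform(t) is added to the
#' pyramidal membrane potential argument wherever v_pyr enters a sigmoid.
#' The first `burnin` seconds are discarded.
#'
#' @param network a [NetworkModel-class].
#' @param params parameter list from [jrParams()].
#' @param drive a [StimulusDrive-class] or NULL.
#' @param duration total simulated time, s (must exceed burnin).
#' @param dt time step, s (default 0.5 ms; must be <= 1 ms).
#' @param burnin discarded initial interval, s.
#' @param seed integer RNG seed.
#' @param recordEvery store every k-th step (output fs = 1/(k dt)).
#' @return a [SimOutput-class] of pyramidal potentials y1 - y2, mV.
#' @export
simulateNetwork <- function(network, params = jrParams(), drive = NULL,
                            duration = 30, dt = 5e-4, burnin = 1,
                            seed = 1L, recordEvery = 1L) {
  if (duration <= burnin) stop("duration must exceed burnin")
  if (dt > 1e-3) stop("dt must be <= 1 ms")
  n <- nrow(network@positions)
  Dreg <- delaySteps(network, dt, params$conductionSpeed)
  storage.mode(Dreg) <- "integer"
  useLocal <- !is.null(network@localW)
  L <- if (useLocal) network@localW else
    methods::as(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(n, n)),
                "dgCMatrix")
  if (is.null(drive)) {
    amp <- numeric(n); shape <- 0L; freq <- 0; on <- 0; off <- 0
  } else {
    if (length(drive@amplitude) != n) stop("drive amplitude length mismatch")
    amp <- drive@amplitude
    shape <- match(drive@shape, c("sinusoid", "dc", "am"))
    freq <- drive@freqHz
    on <- drive@window[1]; off <- drive@window[2]
    if (all(amp == 0)) shape <- 0L
  }
  nSteps <- round(duration / dt)
  burnSteps <- round(burnin / dt)
  # TVB-style additive noise on y4: sd per step sqrt(2 nsig dt_ms) mV/ms
  noiseInc <- 1000 * sqrt(2 * params$noiseSigma * dt * 1000)
  if (params$noiseSigma == 0) noiseInc <- 0
  set.seed(as.integer(seed))
  res <- .jr_simulate(network@weights, Dreg, as.integer(network@region - 1L),
                      L, useLocal,
                      params$A, params$B, params$a, params$b,
                      params$C1, params$C2, params$C3, params$C4,
                      params$v0, params$e0, params$r,
                      params$G, params$pMean, noiseInc,
                      amp, shape, freq, on, off,
                      dt, as.integer(nSteps), as.integer(burnSteps),
                      as.integer(recordEvery))
  new("SimOutput", time = as.numeric(res$time), vpyr = res$vpyr, dt = dt,
      fs = 1 / (dt * recordEvery), seed = as.integer(seed), burnin = burnin)
}

#' Stationary state of an uncoupled noise-free Jansen-Rit node
#'
#' Root of the six stationary equations at constant input `pConst`
#' (1/s), found with uniroot on the reduced scalar fixed-point equation
#' in v = y1 - y2. Used to verify that the integrator settles onto the
#' algebraic equilibrium.
#'
#' @param params parameter list.
#' @param pConst constant pulse-density input, 1/s.
#' @return list(v, y) with the pyramidal potential and the full 6-state
#'   fixed point.
#' @export
jrFixedPoint <- function(params = jrParams(), pConst = 0) {
  S <- function(v) jrSigmoid(v, params)
  g <- function(v) {
    y0 <- params$A / params$a * S(v)
    y1 <- params$A / params$a * (pConst + params$C2 * S(params$C1 * y0))
    y2 <- params$B / params$b * params$C4 * S(params$C3 * y0)
    (y1 - y2) - v
  }
  root <- stats::uniroot(g, c(-100, 100), tol = 1e-12)
  v <- root$root
  y0 <- params$A / params$a * S(v)
  y1 <- params$A / params$a * (pConst + params$C2 * S(params$C1 * y0))
  y2 <- params$B / params$b * params$C4 * S(params$C3 * y0)
  list(v = v, y = c(y0 = y0, y1 = y1, y2 = y2, y3 = 0, y4 = 0, y5 = 0))
}
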