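#' @import methods
#' @importFrom stats fft quantile cor prcomp kmeans sd rnorm runif rlnorm setNames
#' @importFrom utils head read.csv write.csv
#' @useDynLib nibsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Coordinate convention used throughout: right-handed RAS, millimetres,
# 0-based voxel indices, world = origin + index * spacing (voxel centres).

#' TissuePhantom: voxelized multi-shell volume conductor
#'
#' Holds an integer label volume on a rectilinear grid, the tissue
#' conductivity table, and the four scalp landmarks (nasion, inion and the
#' two pre-auricular points) used to anchor electrode placement.
#'
#' @slot labels integer 3D array; 0 is non-conducting background (air).
#' @slot spacing numeric(3), voxel size in mm per axis (> 0).
#' @slot origin numeric(3), world coordinate (mm) of voxel index (0,0,0).
#' @slot tissueTable data.frame with columns `label`, `name`, `sigma`
#'   (scalar conductivity, S/m).
#' @slot landmarks 4x3 numeric matrix, rows nasion/inion/lpa/rpa (mm).
#' @slot meta list of generator metadata (shell radii, seed, ...).
#' @export
setClass("TissuePhantom", representation(
  labels = "array", spacing = "numeric", origin = "numeric",
  tissueTable = "data.frame", landmarks = "matrix", meta = "list"
))

setValidity("TissuePhantom", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  labs <- setdiff(sort(unique(as.integer(object@labels))), 0L)
  if (!all(labs %in% object@tissueTable$label))
    msg <- c(msg, "every nonzero label needs a tissueTable entry")
  if (any(object@tissueTable$sigma <= 0))
    msg <- c(msg, "conductivities must be > 0 for conducting tissues")
  if (!all(c("nasion", "inion", "lpa", "rpa") %in% rownames(object@landmarks)))
    msg <- c(msg, "landmarks must include nasion, inion, lpa, rpa")
  if (length(msg)) msg else TRUE
})

#' CorticalMesh: tessellated cortical surface
#'
#' @slot vertices n x 3 matrix, mm.
#' @slot triangles m x 3 integer matrix (1-based vertex indices).
#' @slot normals n x 3 outward unit normals.
#' @slot region integer(n), region index of each vertex (1..nRegions).
#' @slot nRegions integer(1).
#' @export
setClass("CorticalMesh", representation(
  vertices = "matrix", triangles = "matrix", normals = "matrix",
  region = "integer", nRegions = "integer"
))

setValidity("CorticalMesh", function(object) {
  msg <- character()
  nv <- nrow(object@vertices)
  if (nrow(object@normals) != nv) msg <- c(msg, "one normal per vertex required")
  nrm <- sqrt(rowSums(object@normals^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "normals must be unit length (1e-6)")
  if (any(object@triangles < 1L) || any(object@triangles > nv))
    msg <- c(msg, "triangle indices out of range")
  if (length(object@region) != nv) msg <- c(msg, "one region id per vertex")
  if (length(msg)) msg else TRUE
})

#' Connectome: synthetic structural connectivity
#'
#' @slot weights n x n nonnegative symmetric matrix, zero diagonal.
#' @slot lengths n x n tract lengths, mm (here Euclidean centroid distances).
#' @slot centroids n x 3 region centroids, mm.
#' @slot names character(n) region names.
#' @slot hemisphere integer(n), 1 = left, 2 = right.
#' @export
setClass("Connectome", representation(
  weights = "matrix", lengths = "matrix", centroids = "matrix",
  names = "character", hemisphere = "integer"
))

setValidity("Connectome", function(object) {
  msg <- character()
  w <- object@weights
  if (any(diag(w) != 0)) msg <- c(msg, "weights must have zero diagonal")
  if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
  if (!isSymmetric(unname(w), tol = 1e-12)) msg <- c(msg, "weights must be symmetric")
  if (!isSymmetric(unname(object@lengths), tol = 1e-12)) msg <- c(msg, "lengths must be symmetric")
  if (length(msg)) msg else TRUE
})

#' ElectrodeMontage: labeled scalp electrode set (10-10 nomenclature)
#'
#' @slot electrodes data.frame with columns label, x, y, z (mm), radius (mm).
#' @slot reference character(1), reference electrode label.
#' @export
setClass("ElectrodeMontage", representation(
  electrodes = "data.frame", reference = "character"
))

setValidity("ElectrodeMontage", function(object) {
  msg <- character()
  if (anyDuplicated(object@electrodes$label)) msg <- c(msg, "electrode labels must be unique")
  if (!(object@reference %in% object@electrodes$label))
    msg <- c(msg, "reference must be one of the electrode labels")
  if (length(msg)) msg else TRUE
})

#' TensorField: per-voxel symmetric conductivity/diffusion tensors
#'
#' Symmetric 3x3 tensors stored in 6-component lower-triangular order
#' (xx, xy, yy, xz, yz, zz) as a 4D array (nx, ny, nz, 6).
#'
#' @slot data 4D numeric array, last dimension length 6.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @slot units character(1), "S/m" (conductivity) or "mm^2/s" (diffusion).
#' @slot mask logical 3D array of valid voxels.
#' @export
setClass("TensorField", representation(
  data = "array", spacing = "numeric", origin = "numeric",
  units = "character", mask = "array"
))

setValidity("TensorField", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 6L) msg <- c(msg, "data must be (nx,ny,nz,6)")
  if (!identical(d[1:3], dim(object@mask))) msg <- c(msg, "mask must match grid")
  if (length(msg)) msg else TRUE
})

#' PotentialSolution: electroquasistatic solve result
#'
#' @slot phi 3D array of potentials, volts; NA outside the conducting domain.
#' @slot drive list describing the Dirichlet drive (electrodes, potentials).
#' @slot residual final relative residual of the linear solve.
#' @slot currentA injected current through the source patch, amperes.
#' @slot spacing,origin grid geometry, mm.
#' @export
setClass("PotentialSolution", representation(
  phi = "array", drive = "list", residual = "numeric", currentA = "numeric",
  spacing = "numeric", origin = "numeric"
))

#' EFieldBasis: per-electrode unit-current E-field solutions
#'
#' Each basis entry is the field of one electrode driven against the common
#' reference, rescaled to 1 mA injected current. Any pair field follows by
#' superposition: E(a,b) = basis(a) - basis(b).
#'
#' @slot fields named list of 4D arrays (nx,ny,nz,3), V/m per 1 mA.
#' @slot reference character(1) reference electrode label.
#' @slot mask logical 3D array, conducting domain.
#' @slot spacing,origin grid geometry, mm.
#' @slot meta list: per-electrode residuals and raw injected currents.
#' @export
setClass("EFieldBasis", representation(
  fields = "list", reference = "character", mask = "array",
  spacing = "numeric", origin = "numeric", meta = "list"
))

#' LeadFieldMatrix: reciprocity-derived source-to-sensor map
#'
#' Rows are sensing electrodes (vs the reference), columns are dipole
#' sources at mesh vertices oriented along the vertex normal; entries in
#' V per unit dipole moment (A*m).
#'
#' @slot lf electrodes x sources numeric matrix.
#' @slot electrodes character row labels.
#' @slot reference character(1); its row is identically zero unless the
#'   matrix has been average-referenced.
#' @slot referenced character(1), "electrode" or "average".
#' @export
setClass("LeadFieldMatrix", representation(
  lf = "matrix", electrodes = "character", reference = "character",
  referenced = "character"
))

#' StimConfig: one candidate stimulation configuration
#'
#' Two-channel temporal interference (tTIS) or degenerate single-channel
#' tACS assignment of electrode pairs, currents and frequencies.
#'
#' @slot pair1,pair2 character(2) electrode labels (pair2 empty for tACS).
#' @slot current1,current2 channel currents, mA.
#' @slot freq1,freq2 channel frequencies, Hz.
#' @export
setClass("StimConfig", representation(
  pair1 = "character", pair2 = "character",
  current1 = "numeric", current2 = "numeric",
  freq1 = "numeric", freq2 = "numeric"
))

setValidity("StimConfig", function(object) {
  msg <- character()
  two <- length(object@pair2) == 2L
  if (object@current1 <= 0) msg <- c(msg, "currents must be > 0")
  if (object@freq1 <= 0) msg <- c(msg, "frequencies must be > 0")
  if (two) {
    if (object@current2 <= 0) msg <- c(msg, "currents must be > 0")
    if (object@freq2 <= 0) msg <- c(msg, "frequencies must be > 0")
    if (length(intersect(object@pair1, object@pair2)))
      msg <- c(msg, "channel pairs must be disjoint")
    if (object@freq1 == object@freq2)
      msg <- c(msg, "tTIS channels need distinct frequencies")
  }
  if (length(msg)) msg else TRUE
})

#' ExposureMetrics: M1-M3 scores of one configuration
#'
#' @slot m1 strength: p-th percentile of the QoI in the target, V/m.
#' @slot m2 selectivity: mean target QoI / mean off-target QoI.
#' @slot m3 collateral: fraction of non-target brain above threshold.
#' @slot p percentile used for m1.
#' @slot threshold threshold used for m3, V/m.
#' @slot qoi character, "MEM" or "|E|".
#' @export
setClass("ExposureMetrics", representation(
  m1 = "numeric", m2 = "numeric", m3 = "numeric",
  p = "numeric", threshold = "numeric", qoi = "character"
))

setValidity("ExposureMetrics", function(object) {
  msg <- character()
  if (object@m3 < 0 || object@m3 > 1) msg <- c(msg, "m3 must lie in [0,1]")
  if (object@m1 < 0) msg <- c(msg, "m1 must be >= 0")
  if (object@m2 < 0) msg <- c(msg, "m2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ParetoResult: candidate set with dominance flags and ranking
#'
#' @slot table data.frame: one row per configuration with m1, m2, m3,
#'   pareto (logical), score, rank.
#' @slot configs list of StimConfig in input order.
#' @slot weights numeric(3) last-used objective weights.
#' @export
setClass("ParetoResult", representation(
  table = "data.frame", configs = "list", weights = "numeric"
))

#' NetworkModel: Jansen-Rit network graph
#'
#' @slot mode "region" or "surface".
#' @slot positions n x 3 node positions, mm.
#' @slot normals n x 3 outward unit normals (cortical orthodromic axis).
#' @slot region integer(n) region id per node.
#' @slot weights n x n long-range coupling weights (region weights mapped
#'   to nodes in surface mode); zero diagonal.
#' @slot lengths n x n tract lengths, mm (delays = lengths/speed/dt steps).
#' @slot localW sparse n x n Gaussian local coupling (surface mode) or NULL.
#' @export
setClass("NetworkModel", representation(
  mode = "character", positions = "matrix", normals = "matrix",
  region = "integer", weights = "matrix", lengths = "matrix",
  localW = "ANY"
))

#' StimulusDrive: per-node stimulus description
#'
#' Node amplitudes are lambda * (E . n) in mV (1 V/m x 1 mm = 1 mV); the
#' waveform multiplies the amplitude and is zero outside [on, off).
#'
#' @slot amplitude numeric(n), mV.
#' @slot freqHz waveform frequency (ignored for dc).
#' @slot window numeric(2), on/off time, s.
#' @slot shape "sinusoid", "dc" or "am" (Hann-enveloped sinusoid).
#' @export
setClass("StimulusDrive", representation(
  amplitude = "numeric", freqHz = "numeric", window = "numeric",
  shape = "character"
))

#' SimOutput: simulated pyramidal potentials
#'
#' @slot time numeric, seconds (burn-in removed).
#' @slot vpyr n x length(time) matrix of pyramidal potentials y1-y2, mV.
#' @slot dt integration step, s.
#' @slot fs effective sampling rate of the stored series, Hz.
#' @slot seed integer RNG seed.
#' @slot burnin discarded initial interval, s.
#' @export
setClass("SimOutput", representation(
  time = "numeric", vpyr = "matrix", dt = "numeric", fs = "numeric",
  seed = "integer", burnin = "numeric"
))

setValidity("SimOutput", function(object) {
  if (!all(is.finite(object@vpyr))) return("vpyr contains non-finite values")
  if (ncol(object@vpyr) != length(object@time)) return("time/vpyr mismatch")
  TRUE
})

#' EEGRecord: virtual sensor-space voltages
#'
#' @slot labels channel labels (10-10 names).
#' @slot fs sampling rate, Hz.
#' @slot data channels x time voltage matrix (arbitrary units unless the
#'   source dipole scaling is physical).
#' @slot reference character description of the reference.
#' @export
setClass("EEGRecord", representation(
  labels = "character", fs = "numeric", data = "matrix", reference = "character"
))

#' SpectralResult: PSD / spectrogram / band-power container
#'
#' @slot freq frequencies, Hz.
#' @slot psd channels x freq PSD matrix (power / Hz), or NULL.
#' @slot channelMean numeric channel-averaged PSD, or NULL.
#' @slot spectrogram list(time, freq, power) or NULL.
#' @slot bandPower named numeric per-channel band power, or NULL.
#' @slot meta list of estimator settings.
#' @export
setClass("SpectralResult", representation(
  freq = "numeric", psd = "ANY", channelMean = "ANY",
  spectrogram = "ANY", bandPower = "ANY", meta = "list"
))

#' DFCSeries: sliding-window functional connectivity
#'
#' @slot centers window centre times, s.
#' @slot windowSec window length, s.
#' @slot overlap overlap fraction.
#' @slot fc n x n x nWindows array of Pearson correlation matrices.
#' @slot vectors nWindows x n(n-1)/2 matrix of upper-triangle vectors.
#' @export
setClass("DFCSeries", representation(
  centers = "numeric", windowSec = "numeric", overlap = "numeric",
  fc = "array", vectors = "matrix"
))

#' StateModel: clustered DFC state representation
#'
#' @slot k number of states.
#' @slot centers k x p cluster centres in FC-vector space.
#' @slot stateLabels integer per-window state labels (1..k).
#' @slot occupancy numeric(k), fractions summing to 1.
#' @slot meanDwell mean dwell time per state, s.
#' @slot transitionRate state transitions per second (fluidity proxy).
#' @slot pca list(rotation, sdev, scores, explained) or empty.
#' @export
setClass("StateModel", representation(
  k = "integer", centers = "matrix", stateLabels = "integer",
  occupancy = "numeric", meanDwell = "numeric", transitionRate = "numeric",
  pca = "list"
))
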