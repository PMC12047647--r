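# Accessors and show methods for the core containers.

#' Voxel spacing of a gridded object
#' @param x a TissuePhantom, TensorField, PotentialSolution or EFieldBasis
#' @return numeric(3), mm per axis
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "TissuePhantom", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "TensorField", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "EFieldBasis", function(x) x@spacing)

#' Grid origin (world mm of voxel (0,0,0))
#' @param x a gridded object
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "TissuePhantom", function(x) x@origin)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "TensorField", function(x) x@origin)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "EFieldBasis", function(x) x@origin)

#' Label volume of a phantom
#' @param x a TissuePhantom
#' @export
phantomLabels <- function(x) x@labels

#' Tissue conductivity table of a phantom
#' @param x a TissuePhantom
#' @export
tissueTable <- function(x) x@tissueTable

#' Scalp landmarks (nasion, inion, lpa, rpa) in mm
#' @param x a TissuePhantom
#' @export
scalpLandmarks <- function(x) x@landmarks

#' Electrode table of a montage
#' @param x an ElectrodeMontage
#' @export
electrodeTable <- function(x) x@electrodes

#' Positions of named electrodes
#' @param x an ElectrodeMontage
#' @param labels electrode labels to look up
#' @return length(labels) x 3 matrix of positions, mm
#' @export
electrodePositions <- function(x, labels = NULL) {
  tab <- x@electrodes
  if (is.null(labels)) labels <- tab$label
  idx <- match(labels, tab$label)
  if (anyNA(idx)) stop("unknown electrode label(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  m <- as.matrix(tab[idx, c("x", "y", "z")])
  rownames(m) <- labels
  m
}

#' Mesh vertices / normals / regions
#' @param x a CorticalMesh
#' @export
meshVertices <- function(x) x@vertices
#' @rdname meshVertices
#' @export
meshNormals <- function(x) x@normals
#' @rdname meshVertices
#' @export
meshRegions <- function(x) x@region

#' Connectome weight / length matrices
#' @param x a Connectome
#' @export
scWeights <- function(x) x@weights
#' @rdname scWeights
#' @export
scLengths <- function(x) x@lengths
#' @rdname scWeights
#' @export
scCentroids <- function(x) x@centroids

#' Lead-field matrix as a plain matrix (electrodes x sources)
#' @param x a LeadFieldMatrix
#' @export
leadFieldMatrix <- function(x) x@lf

#' Pyramidal potential matrix of a simulation (nodes x time, mV)
#' @param x a SimOutput
#' @export
pyramidalPotential <- function(x) x@vpyr

#' Voltage matrix of an EEG record (channels x time)
#' @param x an EEGRecord
#' @export
eegData <- function(x) x@data

setMethod("show", "TissuePhantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissuePhantom: %d x %d x %d voxels @ %s mm, %d tissues\n",
              d[1], d[2], d[3], paste(object@spacing, collapse = "x"),
              nrow(object@tissueTable)))
  cat("  tissues:", paste(object@tissueTable$name, collapse = ", "), "\n")
})

setMethod("show", "CorticalMesh", function(object) {
  cat(sprintf("CorticalMesh: %d vertices, %d triangles, %d regions\n",
              nrow(object@vertices), nrow(object@triangles), object@nRegions))
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome: %d regions (%d left / %d right), mean weight %.3g\n",
              nrow(object@weights), sum(object@hemisphere == 1L),
              sum(object@hemisphere == 2L), mean(object@weights)))
})

setMethod("show", "ElectrodeMontage", function(object) {
  cat(sprintf("ElectrodeMontage: %d electrodes (10-10), reference %s\n",
              nrow(object@electrodes), object@reference))
})

setMethod("show", "EFieldBasis", function(object) {
  cat(sprintf("EFieldBasis: %d unit-current (1 mA) fields vs reference %s\n",
              length(object@fields), object@reference))
})

setMethod("show", "LeadFieldMatrix", function(object) {
  cat(sprintf("LeadFieldMatrix: %d electrodes x %d sources (%s-referenced)\n",
              nrow(object@lf), ncol(object@lf), object@referenced))
})

setMethod("show", "StimConfig", function(object) {
  if (length(object@pair2) == 2L) {
    cat(sprintf("StimConfig tTIS: %s-%s %.2f mA @ %g Hz | %s-%s %.2f mA @ %g Hz\n",
                object@pair1[1], object@pair1[2], object@current1, object@freq1,
                object@pair2[1], object@pair2[2], object@current2, object@freq2))
  } else {
    cat(sprintf("StimConfig tACS: %s-%s %.2f mA @ %g Hz\n",
                object@pair1[1], object@pair1[2], object@current1, object@freq1))
  }
})

setMethod("show", "ExposureMetrics", function(object) {
  cat(sprintf("ExposureMetrics (%s): M1 = %.4g V/m (p%g), M2 = %.4g, M3 = %.4g\n",
              object@qoi, object@m1, object@p, object@m2, object@m3))
})

setMethod("show", "ParetoResult", function(object) {
  cat(sprintf("ParetoResult: %d configurations, %d on the Pareto front\n",
              nrow(object@table), sum(object@table$pareto)))
})

setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel (%s): %d nodes, %d regions\n",
              object@mode, nrow(object@positions), length(unique(object@region))))
})

setMethod("show", "SimOutput", function(object) {
  cat(sprintf("SimOutput: %d nodes x %d samples (fs %g Hz, dt %g ms, burn-in %g s)\n",
              nrow(object@vpyr), ncol(object@vpyr), object@fs,
              object@dt * 1000, object@burnin))
})

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf("EEGRecord: %d channels x %d samples @ %g Hz (%s reference)\n",
              nrow(object@data), ncol(object@data), object@fs, object@reference))
})

setMethod("show", "DFCSeries", function(object) {
  cat(sprintf("DFCSeries: %d windows of %g s (overlap %g), %d nodes\n",
              length(object@centers), object@windowSec, object@overlap,
              dim(object@fc)[1]))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k = %d, occupancy %s, transition rate %.3g /s\n",
              object@k, paste(sprintf("%.2f", object@occupancy), collapse = "/"),
              object@transitionRate))
})
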