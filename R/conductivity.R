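# conductivity_map: DTI -> anisotropic conductivity tensors with eigenvalue
# clamping, plus scalar tissue assignment from the phantom table.

# lower-triangular 6-component order used throughout: xx, xy, yy, xz, yz, zz
.tensorToMat <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}
.matToTensor <- function(m) c(m[1, 1], m[2, 1], m[2, 2], m[3, 1], m[3, 2], m[3, 3])

#' Clamp conductivity tensor eigenvalues
#'
#' Two-step post-processing of conductivity eigenvalues: (i) eigenvalues
#' above `sigmaCap` are clamped to that value; (ii) any eigenvalue still
#' exceeding `c` times the smallest (post-step-(i)) eigenvalue is clamped
#' to that threshold. Applied once, not iterated; clamping to exactly
#' `c * min` makes the operation idempotent.
#'
#' @param eigenvalues numeric(3), nonnegative.
#' @param sigmaCap absolute cap, S/m (default 2).
#' @param c maximal anisotropy ratio (default 3).
#' @return numeric(3) clamped eigenvalues (ordering preserved).
#' @examples
#' clampTensorEigenvalues(c(1, 1, 5))        # -> 1 1 2
#' clampTensorEigenvalues(c(0.5, 0.5, 4))    # -> 0.5 0.5 1.5
#' @export
clampTensorEigenvalues <- function(eigenvalues, sigmaCap = 2, c = 3) {
  if (any(eigenvalues < 0)) stop("negative eigenvalue: upstream mapping bug")
  ev <- pmin(eigenvalues, sigmaCap)
  mn <- min(ev)
  if (mn > 0) ev[ev > c * mn] <- c * mn
  ev
}

#' Map a diffusion tensor field to a conductivity tensor field
#'
#' Keeps the DTI eigenvectors and reassigns eigenvalues, either by linear
#' scaling (`sigma_i = k * d_i`) or by the axial/radial database mode
#' (largest eigenvalue -> `axial` S/m, the other two -> `radial` S/m).
#' In linear mode [clampTensorEigenvalues()] is applied voxelwise to tame
#' outlier diffusivities; database magnitudes are prescribed values and
#' are used as given. Non-positive-semidefinite input voxels are masked
#' out with a warning.
#'
#' @param dti a [TensorField-class] with units "mm^2/s".
#' @param mode "linear_scaling" or "database_axial_radial".
#' @param k scaling constant, S*s/(m*mm^2), for linear mode.
#' @param axial,radial conductivities, S/m, for database mode.
#' @param sigmaCap,c clamping parameters.
#' @return a [TensorField-class] with units "S/m".
#' @export
dtiToConductivity <- function(dti, mode = c("linear_scaling",
                                            "database_axial_radial"),
                              k = 0.844 * 1000, axial = 1.1, radial = 0.13,
                              sigmaCap = 2, c = 3) {
  mode <- match.arg(mode)
  out <- dti@data
  mask <- dti@mask
  idx <- which(mask)
  dims <- dim(mask)
  nvox <- prod(dims)
  comp <- matrix(dti@data, nvox, 6)
  bad <- integer(0)
  for (v in idx) {
    m <- .tensorToMat(comp[v, ])
    eg <- eigen(m, symmetric = TRUE)
    if (min(eg$values) < -1e-12 * max(abs(eg$values), 1e-300)) {
      bad <- c(bad, v)
      next
    }
    vals <- pmax(eg$values, 0)            # descending from eigen()
    sig <- switch(mode,
      linear_scaling = clampTensorEigenvalues(k * vals, sigmaCap = sigmaCap,
                                              c = c),
      database_axial_radial = c(axial, radial, radial))
    sm <- eg$vectors %*% diag(sig) %*% t(eg$vectors)
    comp[v, ] <- .matToTensor(sm)
  }
  if (length(bad)) {
    warning(length(bad), " non-PSD voxel(s) masked out")
    mask[bad] <- FALSE
    comp[bad, ] <- 0
  }
  new("TensorField", data = array(comp, c(dims, 6)), spacing = dti@spacing,
      origin = dti@origin, units = "S/m", mask = mask)
}

#' Assemble the full conductivity tensor field of a phantom
#'
#' Every conducting voxel receives the isotropic tensor `sigma * I` from
#' the tissue table; where a white-matter tensor field is supplied, its
#' valid voxels (which must lie inside the WM label) override the scalar
#' assignment.
#'
#' @param phantom a [TissuePhantom-class].
#' @param wmTensor optional [TensorField-class] in S/m restricted to WM.
#' @param wmName tissue name treated as white matter (default "wm").
#' @return a [TensorField-class] in S/m whose mask is the conducting domain.
#' @export
assignTissueConductivity <- function(phantom, wmTensor = NULL, wmName = "wm") {
  labs <- phantom@labels
  dims <- dim(labs)
  tab <- phantom@tissueTable
  present <- setdiff(sort(unique(as.integer(labs))), 0L)
  missing <- setdiff(present, tab$label)
  if (length(missing))
    stop("label(s) missing from tissue table: ", paste(missing, collapse = ", "))
  sigmaOf <- rep(NA_real_, max(tab$label))
  sigmaOf[tab$label] <- tab$sigma
  nvox <- prod(dims)
  comp <- matrix(0, nvox, 6)
  cond <- as.integer(labs) > 0L
  sv <- ifelse(cond, sigmaOf[pmax(as.integer(labs), 1L)], 0)
  comp[, 1] <- sv; comp[, 3] <- sv; comp[, 6] <- sv
  if (!is.null(wmTensor)) {
    if (!identical(dim(wmTensor@mask), dims))
      stop("wmTensor grid does not match phantom grid")
    if (!identical(wmTensor@units, "S/m"))
      stop("wmTensor must be in S/m (run dtiToConductivity first)")
    wmLabel <- tab$label[match(wmName, tab$name)]
    if (is.na(wmLabel)) stop("no tissue named '", wmName, "'")
    tmask <- which(wmTensor@mask)
    outside <- tmask[as.integer(labs)[tmask] != wmLabel]
    if (length(outside))
      stop("tensor mask extends outside the WM label (", length(outside),
           " voxel(s))")
    tcomp <- matrix(wmTensor@data, nvox, 6)
    comp[tmask, ] <- tcomp[tmask, ]
  }
  new("TensorField", data = array(comp, c(dims, 6)), spacing = phantom@spacing,
      origin = phantom@origin, units = "S/m",
      mask = array(cond, dims))
}

#' Synthetic radially-oriented white-matter diffusion tensors
#'
#' Test/demo generator: prolate tensors whose principal axis points along
#' the radial (fiber-like) direction inside the WM shell, with seeded
#' log-normal jitter on the eigenvalues. Units mm^2/s.
#'
#' @param phantom a [TissuePhantom-class] with a "wm" shell.
#' @param dAxial,dRadial axial/radial diffusivities, mm^2/s.
#' @param jitterSd sdlog of the eigenvalue jitter.
#' @param seed integer RNG seed.
#' @return a [TensorField-class] with units "mm^2/s" masked to WM.
#' @export
synthFiberTensors <- function(phantom, dAxial = 1.7e-3, dRadial = 3e-4,
                              jitterSd = 0.1, seed = 1L) {
  labs <- phantom@labels
  dims <- dim(labs)
  wmLabel <- phantom@tissueTable$label[match("wm", phantom@tissueTable$name)]
  if (is.na(wmLabel)) stop("phantom has no 'wm' tissue")
  idx <- which(as.integer(labs) == wmLabel)
  sp <- phantom@spacing; or <- phantom@origin
  ijk <- arrayInd(idx, dims) - 1L
  xyz <- sweep(sweep(ijk, 2, sp, "*"), 2, or, "+")
  rn <- sqrt(rowSums(xyz^2))
  rn[rn < 1e-9] <- 1
  u <- xyz / rn                               # radial unit fiber direction
  set.seed(as.integer(seed))
  ja <- stats::rlnorm(length(idx), 0, jitterSd)
  jr <- stats::rlnorm(length(idx), 0, jitterSd)
  da <- dAxial * ja
  dr <- dRadial * jr
  nvox <- prod(dims)
  comp <- matrix(0, nvox, 6)
  # D = dr * I + (da - dr) * u u'
  comp[idx, 1] <- dr + (da - dr) * u[, 1]^2
  comp[idx, 2] <- (da - dr) * u[, 1] * u[, 2]
  comp[idx, 3] <- dr + (da - dr) * u[, 2]^2
  comp[idx, 4] <- (da - dr) * u[, 1] * u[, 3]
  comp[idx, 5] <- (da - dr) * u[, 2] * u[, 3]
  comp[idx, 6] <- dr + (da - dr) * u[, 3]^2
  mask <- array(FALSE, dims)
  mask[idx] <- TRUE
  new("TensorField", data = array(comp, c(dims, 6)), spacing = sp,
      origin = or, units = "mm^2/s", mask = mask)
}
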