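# Shared fixtures: small analytic grids and phantoms built in code.

# homogeneous/isotropic box tensor field (dims in voxels, h in mm)
boxField <- function(dims, h = 2, sigma = 1, mask = NULL) {
  comp <- array(0, c(dims, 6))
  sv <- if (length(sigma) == 1) array(sigma, dims) else sigma
  comp[, , , 1] <- sv; comp[, , , 3] <- sv; comp[, , , 6] <- sv
  if (is.null(mask)) mask <- array(TRUE, dims)
  new("TensorField", data = comp, spacing = rep(h, 3), origin = c(0, 0, 0),
      units = "S/m", mask = mask)
}

# constant full-tensor box field
boxTensorField <- function(dims, h, M, mask = NULL) {
  comp <- array(0, c(dims, 6))
  comp[, , , 1] <- M[1, 1]; comp[, , , 2] <- M[1, 2]; comp[, , , 3] <- M[2, 2]
  comp[, , , 4] <- M[1, 3]; comp[, , , 5] <- M[2, 3]; comp[, , , 6] <- M[3, 3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  new("TensorField", data = comp, spacing = rep(h, 3), origin = c(0, 0, 0),
      units = "S/m", mask = mask)
}

# x-face patches of a box grid
facePatches <- function(dims) {
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  list(A = which(ijk[, 1] == 1), B = which(ijk[, 1] == dims[1]))
}

# small 4-shell phantom that resolves at 4 mm spacing
coarsePhantom <- function(spacing = 4) {
  buildSpherePhantom(c(92, 84, 78, 74, 66), c(0.4, 0.01, 1.8, 0.3, 0.15),
                     spacing = spacing)
}

# single-node Jansen-Rit "network"
singleNode <- function() {
  new("NetworkModel", mode = "region", positions = matrix(0, 1, 3),
      normals = matrix(c(0, 0, 1), 1, 3), region = 1L,
      weights = matrix(0, 1, 1), lengths = matrix(0, 1, 1), localW = NULL)
}

# random SPD 3x3 matrix
randomSpd <- function() {
  m <- matrix(rnorm(9), 3, 3)
  crossprod(m) + diag(3) * 0.1
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# two-regime synthetic signal set: `n` nodes, regime A = two synchronized
# blocks, regime B = global synchrony, alternating segments
twoRegimeSignals <- function(n = 12, fs = 100, segSec = 20, nSeg = 4,
                             seed = 1) {
  set.seed(seed)
  nt <- fs * segSec * nSeg
  tt <- seq_len(nt) / fs
  x <- matrix(rnorm(n * nt, sd = 0.2), n, nt)
  blockA <- rep(c(TRUE, FALSE), each = n / 2)
  for (s in seq_len(nSeg)) {
    sel <- ((s - 1) * fs * segSec + 1):(s * fs * segSec)
    if (s %% 2 == 1) {
      c1 <- sin(2 * pi * 3 * tt[sel]); c2 <- cos(2 * pi * 5 * tt[sel])
      x[blockA, sel] <- x[blockA, sel] + rep(c1, each = n / 2)
      x[!blockA, sel] <- x[!blockA, sel] + rep(c2, each = n / 2)
    } else {
      cg <- sin(2 * pi * 4 * tt[sel])
      x[, sel] <- x[, sel] + rep(cg, each = n)
    }
  }
  list(signals = x, fs = fs, segment = rep(rep(1:2, length.out = nSeg),
                                           each = segSec))
}
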