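# em_forward: electroquasistatic finite-volume solver on the voxel grid.
#
# Discretization: 7-point two-point-flux stencil with harmonic-mean face
# conductivities for the tensor diagonal; symmetric corner-coupling
# stencil (energy-form Hessian of central-difference cross products) for
# the tensor off-diagonals, dropped for cells whose four in-plane
# neighbours are not all conducting. Linear potentials in homogeneous
# anisotropic media are reproduced exactly. Assembly is in SI units
# (metres), so face conductances are in siemens and fluxes in amperes.

# map voxel linear index shifts along each axis
.axisShift <- function(dims) c(1L, dims[1], dims[1] * dims[2])

# Assemble the global FV matrix over all conducting cells.
# Returns cells (voxel linear indices), cellId (array), A (dgCMatrix).
.assembleSystem <- function(sigma) {
  dims <- dim(sigma@mask)
  hs <- sigma@spacing * 1e-3                     # metres
  V <- prod(hs)
  nvox <- prod(dims)
  comp <- matrix(sigma@data, nvox, 6)
  cond <- as.vector(sigma@mask)
  cells <- which(cond)
  nc <- length(cells)
  cellId <- integer(nvox)
  cellId[cells] <- seq_len(nc)
  sh <- .axisShift(dims)
  diagComp <- c(1L, 3L, 6L)                      # xx, yy, zz
  ii <- jj <- integer(0); xx <- numeric(0)
  idxArr <- arrayInd(cells, dims)
  for (ax in 1:3) {
    ok <- idxArr[, ax] < dims[ax]
    a <- cells[ok]
    b <- a + sh[ax]
    keep <- cond[b]
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    sa <- comp[a, diagComp[ax]]
    sb <- comp[b, diagComp[ax]]
    g <- ifelse(sa + sb > 0, 2 * sa * sb / (sa + sb), 0) *
      (V / hs[ax]^2)                             # face area / h = V / h^2
    ia <- cellId[a]; ib <- cellId[b]
    ii <- c(ii, ia, ib, ia, ib)
    jj <- c(jj, ia, ib, ib, ia)
    xx <- c(xx, g, g, -g, -g)
  }
  offComp <- rbind(c(1L, 2L, 2L), c(1L, 3L, 4L), c(2L, 3L, 5L))  # p,q,comp
  if (any(comp[cells, c(2, 4, 5)] != 0)) {
    for (kk in 1:3) {
      p <- offComp[kk, 1]; q <- offComp[kk, 2]; cp <- offComp[kk, 3]
      cen <- cells[idxArr[, p] > 1 & idxArr[, p] < dims[p] &
                   idxArr[, q] > 1 & idxArr[, q] < dims[q]]
      if (!length(cen)) next
      ap <- cen + sh[p]; am <- cen - sh[p]
      aq <- cen + sh[q]; am2 <- cen - sh[q]
      keep <- cond[ap] & cond[am] & cond[aq] & cond[am2] &
        comp[cen, cp] != 0
      cen <- cen[keep]
      if (!length(cen)) next
      ap <- ap[keep]; am <- am[keep]; aq <- aq[keep]; am2 <- am2[keep]
      kap <- comp[cen, cp] * V / (2 * hs[p] * hs[q]) / 2
      i1 <- cellId[ap]; i2 <- cellId[am]; j1 <- cellId[aq]; j2 <- cellId[am2]
      ii <- c(ii, i1, i1, i2, i2, j1, j2, j1, j2)
      jj <- c(jj, j1, j2, j1, j2, i1, i1, i2, i2)
      xx <- c(xx, kap, -kap, -kap, kap, kap, -kap, -kap, kap)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nc, nc))
  list(A = A, cells = cells, cellId = cellId, dims = dims, hs = hs)
}

# flood-fill connectivity of the conducting mask between two cell sets,
# via whole-array dilations (face neighbourhood)
.patchesConnected <- function(mask, cellsA, cellsB) {
  reach <- array(FALSE, dim(mask))
  reach[cellsA] <- TRUE
  repeat {
    grow <- reach
    for (ax in 1:3)
      grow <- grow | .shiftArr(reach, ax, 1L) | .shiftArr(reach, ax, -1L)
    grow <- grow & mask
    if (any(grow[cellsB])) return(TRUE)
    if (sum(grow) == sum(reach)) return(FALSE)
    reach <- grow
  }
}

#' Scalp voxel patch of an electrode
#'
#' Conducting voxels of the outermost (scalp) tissue within the electrode
#' pad radius of the electrode centre; used as a Dirichlet equipotential
#' patch.
#'
#' @param phantom a [TissuePhantom-class].
#' @param montage an [ElectrodeMontage-class].
#' @param label electrode label.
#' @return integer vector of voxel linear indices.
#' @export
electrodePatch <- function(phantom, montage, label) {
  pos <- electrodePositions(montage, label)[1, ]
  rad <- montage@electrodes$radius[match(label, montage@electrodes$label)]
  labs <- phantom@labels
  dims <- dim(labs)
  scalpLabel <- phantom@tissueTable$label[1]
  idx <- which(as.integer(labs) == scalpLabel)
  ijk <- arrayInd(idx, dims) - 1L
  xyz <- sweep(sweep(ijk, 2, phantom@spacing, "*"), 2, phantom@origin, "+")
  d2 <- (xyz[, 1] - pos[1])^2 + (xyz[, 2] - pos[2])^2 + (xyz[, 3] - pos[3])^2
  cellsIn <- idx[d2 <= rad^2]
  if (!length(cellsIn))
    stop("electrode ", label, " has no scalp voxels within its radius")
  cellsIn
}

#' Solve the electroquasistatic potential for a two-patch Dirichlet drive
#'
#' Finite-volume discretization of div(sigma grad phi) = 0 on the
#' conducting domain with two Dirichlet equipotential patches and zero
#' normal flux elsewhere, solved with Jacobi-preconditioned conjugate
#' gradients. The injected current is obtained by summing the discrete
#' residual fluxes over each patch.
#'
#' @param sigma a [TensorField-class] in S/m; the mask defines the
#'   conducting domain.
#' @param patchA,patchB integer voxel linear indices of the two patches.
#' @param phiA,phiB applied patch potentials, V (default +/- 0.5).
#' @param tol relative residual tolerance of the linear solve.
#' @param maxit maximal CG iterations.
#' @param checkConnected verify the two patches are in one conducting
#'   component before solving.
#' @param driveNames optional electrode labels for bookkeeping.
#' @return a [PotentialSolution-class]; `currentA` is the current into
#'   patch A in amperes (patch B carries the opposite current).
#' @export
solvePotential <- function(sigma, patchA, patchB, phiA = 0.5, phiB = -0.5,
                           tol = 1e-8, maxit = 10000L, checkConnected = TRUE,
                           driveNames = c("A", "B")) {
  if (length(intersect(patchA, patchB))) stop("electrode patches overlap")
  sys <- .assembleSystem(sigma)
  nc <- length(sys$cells)
  idA <- sys$cellId[patchA]; idB <- sys$cellId[patchB]
  if (any(idA == 0) || any(idB == 0)) stop("patch voxels outside conducting domain")
  if (checkConnected && !.patchesConnected(sigma@mask, patchA, patchB))
    stop("conducting domain is disconnected between the two patches")
  fixed <- c(idA, idB)
  phiD <- c(rep(phiA, length(idA)), rep(phiB, length(idB)))
  free <- setdiff(seq_len(nc), fixed)
  Auu <- sys$A[free, free, drop = FALSE]
  Aud <- sys$A[free, fixed, drop = FALSE]
  b <- as.numeric(-Aud %*% phiD)
  sol <- .cg_solve(methods::as(Auu, "dgCMatrix"), b, tol, as.integer(maxit))
  if (sol$relres > tol)
    stop(sprintf("solver did not converge: relative residual %.3g after %d iterations",
                 sol$relres, sol$iters))
  phiAll <- numeric(nc)
  phiAll[free] <- sol$x
  phiAll[fixed] <- phiD
  # discrete patch currents: net outflux of the Dirichlet cells
  r <- as.numeric(sys$A %*% phiAll)
  iA <- sum(r[idA]); iB <- sum(r[idB])
  phi <- array(NA_real_, sys$dims)
  phi[sys$cells] <- phiAll
  new("PotentialSolution", phi = phi,
      drive = list(names = driveNames, phi = c(phiA, phiB),
                   patchA = patchA, patchB = patchB,
                   currentB = iB,
                   patchCurrentsA = r[idA], patchCurrentsB = r[idB]),
      residual = sol$relres, currentA = iA,
      spacing = sigma@spacing, origin = sigma@origin)
}

#' Solve the potential of a discrete current dipole (two opposite monopoles)
#'
#' Pure-Neumann forward solve with a unit point source and sink in two
#' voxels; the potential is gauged by pinning one conducting cell to zero.
#' Used as the independent forward oracle for the reciprocity lead field.
#'
#' @param sigma a [TensorField-class] in S/m.
#' @param cellPlus,cellMinus voxel linear indices of the +/- monopoles.
#' @param currentA monopole strength, A.
#' @param tol,maxit solver controls.
#' @return a [PotentialSolution-class] (gauge: first conducting cell at 0 V).
#' @export
solveDipole <- function(sigma, cellPlus, cellMinus, currentA = 1e-6,
                        tol = 1e-8, maxit = 20000L) {
  sys <- .assembleSystem(sigma)
  nc <- length(sys$cells)
  ip <- sys$cellId[cellPlus]; im <- sys$cellId[cellMinus]
  if (ip == 0 || im == 0) stop("dipole cells outside conducting domain")
  b <- numeric(nc)
  b[ip] <- currentA
  b[im] <- -currentA
  pin <- 1L
  free <- setdiff(seq_len(nc), pin)
  Auu <- sys$A[free, free, drop = FALSE]
  sol <- .cg_solve(methods::as(Auu, "dgCMatrix"), b[free], tol, as.integer(maxit))
  if (sol$relres > tol)
    stop(sprintf("dipole solve did not converge: relres %.3g", sol$relres))
  phiAll <- numeric(nc)
  phiAll[free] <- sol$x
  phi <- array(NA_real_, sys$dims)
  phi[sys$cells] <- phiAll
  new("PotentialSolution", phi = phi,
      drive = list(names = c("dipole+", "dipole-"), currentA = currentA,
                   cellPlus = cellPlus, cellMinus = cellMinus),
      residual = sol$relres, currentA = currentA,
      spacing = sigma@spacing, origin = sigma@origin)
}

#' E-field from a potential solution
#'
#' E = -grad(phi): central differences in the interior, one-sided at the
#' tissue boundary, zero outside the conducting domain.
#'
#' @param sol a [PotentialSolution-class].
#' @return 4D array (nx, ny, nz, 3) in V/m.
#' @export
efieldFromPotential <- function(sol) {
  phi <- sol@phi
  dims <- dim(phi)
  hmm <- sol@spacing                     # mm
  E <- array(0, c(dims, 3))
  have <- !is.na(phi)
  phi0 <- phi; phi0[!have] <- 0
  for (ax in 1:3) {
    up <- .shiftArr(phi0, ax, -1L); hup <- .shiftArr(have, ax, -1L)
    dn <- .shiftArr(phi0, ax, +1L); hdn <- .shiftArr(have, ax, +1L)
    g <- array(0, dims)
    both <- have & hup & hdn
    g[both] <- (up[both] - dn[both]) / (2 * hmm[ax])
    onlyUp <- have & hup & !hdn
    g[onlyUp] <- (up[onlyUp] - phi0[onlyUp]) / hmm[ax]
    onlyDn <- have & !hup & hdn
    g[onlyDn] <- (phi0[onlyDn] - dn[onlyDn]) / hmm[ax]
    E[, , , ax] <- -g * 1000             # V/mm -> V/m
  }
  E
}

# shift an array along axis by s voxels (fill with 0/FALSE)
.shiftArr <- function(x, ax, s) {
  dims <- dim(x)
  out <- array(if (is.logical(x)) FALSE else 0, dims)
  n <- dims[ax]
  from <- seq_len(n - abs(s))
  if (s < 0) { src <- from + abs(s); dst <- from } else { src <- from; dst <- from + s }
  ixS <- ixD <- list(quote(expr =), quote(expr =), quote(expr =))
  ixS[[ax]] <- src; ixD[[ax]] <- dst
  out[ixD[[1]], ixD[[2]], ixD[[3]]] <- x[ixS[[1]], ixS[[2]], ixS[[3]]]
  out
}

#' Pre-compute the per-electrode unit-current E-field basis
#'
#' One two-patch solve per non-reference electrode (electrode driven
#' positive against the reference), each rescaled to 1 mA injected
#' current. Any electrode pair's field then follows by superposition:
#' `basisField(basis, a) - basisField(basis, b)`.
#'
#' @param sigma a [TensorField-class] in S/m.
#' @param phantom the [TissuePhantom-class] (for patch geometry).
#' @param montage an [ElectrodeMontage-class].
#' @param labels electrodes to include (default: all non-reference).
#' @param tol solver tolerance.
#' @param verbose print progress per electrode.
#' @return an [EFieldBasis-class]
#' @export
computeFieldBasis <- function(sigma, phantom, montage, labels = NULL,
                              tol = 1e-8, verbose = FALSE) {
  ref <- montage@reference
  if (is.null(labels)) labels <- setdiff(montage@electrodes$label, ref)
  labels <- setdiff(labels, ref)
  refPatch <- electrodePatch(phantom, montage, ref)
  fields <- list()
  patches <- list()
  residuals <- currents <- numeric(0)
  first <- TRUE
  for (lab in labels) {
    patch <- electrodePatch(phantom, montage, lab)
    sol <- solvePotential(sigma, patch, refPatch, tol = tol,
                          checkConnected = first,
                          driveNames = c(lab, ref))
    first <- FALSE
    E <- efieldFromPotential(sol)
    scale <- 1e-3 / sol@currentA        # rescale to 1 mA injected
    fields[[lab]] <- E * scale
    residuals[lab] <- sol@residual
    currents[lab] <- sol@currentA
    # per-cell current distribution over the two patches (the discrete
    # reciprocal sampling functional of this electrode pair)
    patches[[lab]] <- list(
      cells = patch, w = sol@drive$patchCurrentsA / sol@currentA,
      refCells = refPatch, wRef = sol@drive$patchCurrentsB / sol@drive$currentB)
    if (verbose) message(sprintf("  basis %s: I = %.3g mA, relres %.2g",
                                 lab, sol@currentA * 1e3, sol@residual))
  }
  new("EFieldBasis", fields = fields, reference = ref, mask = sigma@mask,
      spacing = sigma@spacing, origin = sigma@origin,
      meta = list(residuals = residuals, rawCurrentsA = currents,
                  patches = patches))
}

#' Field of one electrode (or electrode pair) from the basis
#'
#' @param basis an [EFieldBasis-class].
#' @param label electrode label; the reference returns a zero field.
#' @param against optional second label: returns the pair field
#'   `basis(label) - basis(against)` (1 mA from `label` to `against`).
#' @return 4D array (nx, ny, nz, 3), V/m per 1 mA.
#' @export
basisField <- function(basis, label, against = NULL) {
  get1 <- function(lab) {
    if (lab == basis@reference)
      return(array(0, c(dim(basis@mask), 3)))
    f <- basis@fields[[lab]]
    if (is.null(f)) stop("electrode not in basis: ", lab)
    f
  }
  out <- get1(label)
  if (!is.null(against)) out <- out - get1(against)
  out
}

# trilinear interpolation of a (nx,ny,nz,3) field at world points (mm)
.interpField <- function(field, origin, spacing, pts) {
  dims <- dim(field)[1:3]
  u <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")  # 0-based cont. index
  i0 <- floor(u)
  f <- u - i0
  bad <- i0 < 0 | i0 > matrix(dims - 2, nrow(u), 3, byrow = TRUE)
  if (any(bad)) stop("point(s) outside interpolation grid: ",
                     paste(which(rowSums(bad) > 0), collapse = ", "))
  out <- matrix(0, nrow(pts), 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    lin <- (i0[, 1] + dx) + dims[1] * (i0[, 2] + dy) +
      dims[1] * dims[2] * (i0[, 3] + dz) + 1
    for (k in 1:3) {
      comp <- field[, , , k]
      out[, k] <- out[, k] + w * comp[lin]
    }
  }
  out
}

#' Sample a basis or exposure field at arbitrary points
#'
#' Trilinear interpolation of the vector components at world coordinates.
#'
#' @param field 4D array (nx,ny,nz,3).
#' @param basis an [EFieldBasis-class] providing grid geometry.
#' @param pts n x 3 matrix of points, mm.
#' @return n x 3 matrix of field vectors.
#' @export
sampleField <- function(field, basis, pts) {
  .interpField(field, basis@origin, basis@spacing, pts)
}

#' Reciprocity lead field from an E-field basis
#'
#' For each sensing electrode e and each mesh vertex l with outward
#' normal n_l, the lead-field entry is `-E_e(r_l) . n_l / I_e`, where
#' E_e is the unit-current (1 mA) basis field of e driven positive
#' against the reference; entries are in V per unit dipole moment (A m).
#' The sign convention is such that a dipole whose moment points toward
#' electrode e raises the potential read at e (vs the reference). The
#' reference row is identically zero.
#'
#' @param basis an [EFieldBasis-class].
#' @param mesh a [CorticalMesh-class]; all vertices must lie inside the
#'   conducting domain.
#' @return a [LeadFieldMatrix-class] (electrode-referenced).
#' @export
leadFieldReciprocity <- function(basis, mesh) {
  labs <- names(basis@fields)
  pts <- mesh@vertices
  # vertices must be in conducting voxels
  dims <- dim(basis@mask)
  ijk <- round(sweep(sweep(pts, 2, basis@origin, "-"), 2, basis@spacing, "/"))
  lin <- ijk[, 1] + dims[1] * ijk[, 2] + dims[1] * dims[2] * ijk[, 3] + 1
  bad <- which(!basis@mask[lin])
  if (length(bad))
    stop("mesh vertices outside conducting domain: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  lf <- matrix(0, length(labs) + 1L, nrow(pts))
  for (k in seq_along(labs)) {
    Ev <- .interpField(basis@fields[[labs[k]]], basis@origin, basis@spacing, pts)
    lf[k, ] <- -rowSums(Ev * mesh@normals) / 1e-3
  }
  electrodes <- c(labs, basis@reference)
  rownames(lf) <- electrodes
  new("LeadFieldMatrix", lf = lf, electrodes = electrodes,
      reference = basis@reference, referenced = "electrode")
}

#' Average-reference a lead field
#' @param lf a [LeadFieldMatrix-class]
#' @return the lead field with zero column means ("average" referenced)
#' @export
averageReference <- function(lf) {
  m <- sweep(lf@lf, 2, colMeans(lf@lf))
  new("LeadFieldMatrix", lf = m, electrodes = lf@electrodes,
      reference = lf@reference, referenced = "average")
}
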