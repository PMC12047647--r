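# phantom_factory: deterministic generators for every input the pipeline
# needs -- voxel phantom, 10-10 montage, cortical mesh, connectome.

.defaultTissueNames <- c("scalp", "skull", "csf", "gm", "wm")

#' Default tissue conductivity table
#'
#' Reads the packaged low-frequency conductivity defaults
#' (`inst/extdata/tissue_conductivities.csv`); users can pass their own
#' table in the same format anywhere a conductivity vector is accepted.
#'
#' @param path CSV with columns name, sigma (S/m); default the packaged
#'   table.
#' @return data.frame with columns name and sigma.
#' @export
defaultTissueTable <- function(path = system.file("extdata",
                                                  "tissue_conductivities.csv",
                                                  package = "nibsim")) {
  read.csv(path, stringsAsFactors = FALSE)[, c("name", "sigma")]
}

#' Build a nested spherical multi-shell head phantom
#'
#' Constructs a voxelized volume conductor made of concentric shells
#' (outermost first; by default scalp, skull, CSF, GM, WM) centred at the
#' world origin, with scalp landmarks on the equator (nasion at +y, inion
#' at -y, pre-auricular points at +/-x).
#'
#' @param radii numeric, outer radius of each shell in mm, strictly
#'   decreasing outer to inner.
#' @param conductivities numeric, scalar conductivity per shell, S/m.
#' @param spacing voxel size, mm (isotropic).
#' @param names tissue names, outer to inner.
#' @param seed integer; kept for interface symmetry with the other
#'   generators (the sphere phantom is fully deterministic).
#' @return a [TissuePhantom-class]
#' @examples
#' ph <- buildSpherePhantom(c(46, 43, 40, 39, 35),
#'                          c(0.4, 0.01, 1.8, 0.3, 0.15), spacing = 2)
#' @export
buildSpherePhantom <- function(radii, conductivities, spacing = 2,
                               names = .defaultTissueNames[seq_along(radii)],
                               seed = 1L) {
  if (length(radii) != length(conductivities))
    stop("radii and conductivities must have equal length")
  if (length(radii) > 1 && any(diff(radii) >= 0))
    stop("radii must be strictly decreasing outer to inner")
  thick <- c(-diff(radii), radii[length(radii)])
  if (any(thick < spacing)) {
    k <- which(thick < spacing)[1]
    stop(sprintf("shell '%s' (%.3g mm) is thinner than one voxel (%.3g mm)",
                 names[k], thick[k], spacing))
  }
  R <- radii[1]
  half <- ceiling(R / spacing) + 1L
  n <- 2L * half + 1L
  coord <- (seq_len(n) - 1L - half) * spacing    # world mm, centre voxel at 0
  origin <- rep(coord[1], 3)
  r2 <- outer(outer(coord^2, coord^2, "+"), coord^2, "+")
  r <- sqrt(r2)
  labels <- array(0L, dim = c(n, n, n))
  for (k in seq_along(radii)) labels[r <= radii[k]] <- k  # inner overwrites
  landmarks <- rbind(nasion = c(0, R, 0), inion = c(0, -R, 0),
                     lpa = c(-R, 0, 0), rpa = c(R, 0, 0))
  tab <- data.frame(label = seq_along(radii), name = names,
                    sigma = conductivities, stringsAsFactors = FALSE)
  new("TissuePhantom", labels = labels, spacing = rep(spacing, 3),
      origin = origin, tissueTable = tab, landmarks = landmarks,
      meta = list(radii = radii, seed = as.integer(seed), kind = "sphere"))
}

# Shell radii helper: outer/inner radius of a named tissue, mm.
.shellRadii <- function(phantom, name) {
  radii <- phantom@meta$radii
  if (is.null(radii)) stop("phantom has no shell radius metadata")
  k <- match(name, phantom@tissueTable$name)
  if (is.na(k)) stop("no tissue named '", name, "'")
  c(outer = radii[k], inner = if (k < length(radii)) radii[k + 1] else 0)
}

# spherical linear interpolation between unit vectors
.slerp <- function(u, v, f) {
  w <- sum(u * v)
  w <- max(-1, min(1, w))
  th <- acos(w)
  if (th < 1e-12) return(matrix(rep(u, length(f)), ncol = 3, byrow = TRUE))
  s <- sin(th)
  out <- outer(sin((1 - f) * th) / s, u) + outer(sin(f * th) / s, v)
  out / sqrt(rowSums(out^2))
}

#' Place a 10-10 electrode montage on the phantom scalp
#'
#' Reconstructs the international 10-10 layout from the four scalp
#' landmarks: Cz sits at the crossing of the nasion-inion and
#' pre-auricular geodesics, the midline and coronal chains subdivide those
#' geodesics in 10% arc-length steps, the outer (10%) ring carries the
#' Fp1/AF7/.../O1 chain, and the intermediate rows interpolate along
#' great-circle arcs between the ring and the midline. For the spherical
#' phantoms generated by this package the geodesics are exact great
#' circles in the landmark-derived frame.
#'
#' @param phantom a [TissuePhantom-class] with landmarks.
#' @param radiusMm electrode pad radius, mm; default is a circular 3 cm^2
#'   pad (radius ~9.77 mm).
#' @param reference reference electrode label (default "Cz").
#' @return an [ElectrodeMontage-class]
#' @export
placeElectrodes1010 <- function(phantom, radiusMm = sqrt(300 / pi),
                                reference = "Cz") {
  lm <- phantom@landmarks
  ctr <- colMeans(lm)
  ey <- lm["nasion", ] - lm["inion", ]
  ex <- lm["rpa", ] - lm["lpa", ]
  if (sqrt(sum(ex^2)) < 1e-9 || sqrt(sum(ey^2)) < 1e-9)
    stop("degenerate landmarks")
  ey <- ey / sqrt(sum(ey^2))
  ex <- ex - sum(ex * ey) * ey
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("degenerate (collinear) landmarks")
  ex <- ex / nx
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- mean(sqrt(rowSums(sweep(lm, 2, ctr)^2)))
  # unit-sphere coordinates in the landmark frame; world = ctr + R * (x ex + ...)
  toWorld <- function(p) {
    p <- p / sqrt(sum(p^2))
    ctr + R * (p[1] * ex + p[2] * ey + p[3] * ez)
  }
  sag <- function(f) c(0, cos(pi * f), sin(pi * f))     # nasion -> Cz -> inion
  cor_ <- function(f) c(-cos(pi * f), 0, sin(pi * f))   # lpa -> Cz -> rpa
  z0 <- sin(0.1 * pi); rho <- cos(0.1 * pi)
  ring <- function(f, side) c(side * rho * sin(pi * f), rho * cos(pi * f), z0)

  pos <- list()
  midLab <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz")
  for (i in seq_along(midLab)) pos[[midLab[i]]] <- sag(0.1 * (i))
  corLab <- c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")
  for (i in seq_along(corLab)) pos[[corLab[i]]] <- cor_(0.1 * i)
  ringL <- c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1")
  ringR <- c("Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2")
  for (i in seq_along(ringL)) {
    pos[[ringL[i]]] <- ring(0.1 * i, -1)
    pos[[ringR[i]]] <- ring(0.1 * i, +1)
  }
  rows <- list(AF = c("AF7", "AF8"), F = c("F7", "F8"), FC = c("FT7", "FT8"),
               CP = c("TP7", "TP8"), P = c("P7", "P8"), PO = c("PO7", "PO8"))
  for (rw in names(rows)) {
    lr <- rows[[rw]]
    mid <- pos[[paste0(rw, "z")]]
    lft <- .slerp(pos[[lr[1]]], mid, c(0.25, 0.5, 0.75))
    rgt <- .slerp(pos[[lr[2]]], mid, c(0.25, 0.5, 0.75))
    lab <- function(k) paste0(rw, k)
    for (j in 1:3) {
      pos[[lab(c(5, 3, 1)[j])]] <- lft[j, ]
      pos[[lab(c(6, 4, 2)[j])]] <- rgt[j, ]
    }
  }
  labs <- names(pos)
  xyz <- t(vapply(pos, toWorld, numeric(3)))
  tab <- data.frame(label = labs, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    radius = radiusMm, stringsAsFactors = FALSE,
                    row.names = NULL)
  new("ElectrodeMontage", electrodes = tab, reference = reference)
}

# deterministic area-uniform seed directions per hemisphere (unit vectors);
# left hemisphere is x < 0.  Used by both the mesh sectorization and the
# connectome so that region indices coincide.
.regionSeedDirections <- function(nRegions) {
  if (nRegions %% 2L != 0L) stop("nRegions must be even")
  m <- nRegions / 2L
  k <- seq_len(m)
  ca <- 1 - (k - 0.5) / m           # cos(angle from -x axis), area-uniform
  sa <- sqrt(pmax(0, 1 - ca^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (k - 1) * golden
  left <- cbind(-ca, sa * cos(phi), sa * sin(phi))
  right <- left
  right[, 1] <- -right[, 1]
  dirs <- rbind(left, right)
  list(dirs = dirs, hemisphere = rep(1:2, each = m))
}

# icosphere at given subdivision level (12, 42, 162, 642, 2562, ... vertices)
.icosphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid <- new.env()
    verts <- v
    getMid <- function(a, b) {
      key <- edgeKey(a, b)
      idx <- mid[[key]]
      if (is.null(idx)) {
        p <- verts[a, ] + verts[b, ]
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        idx <- nrow(verts)
        mid[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, cc); ca <- getMid(cc, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Tessellate the cortical (mid-GM) surface of a sphere phantom
#'
#' Produces a quasi-uniform icosphere triangulation of the mid-gray-matter
#' sphere with outward radial normals, and assigns each vertex to one of
#' `nRegions` equal-solid-angle sectors per hemisphere (the same sectors
#' that [synthConnectome()] uses as region centroids, so region indices
#' match between mesh and connectome).
#'
#' @param phantom a [TissuePhantom-class] with a "gm" shell.
#' @param nVertices requested vertex count (>= 12); rounded up to the next
#'   icosphere subdivision level (12, 42, 162, 642, 2562, ...).
#' @param nRegions even region count for sectorization (default 84).
#' @param seed integer; kept for interface symmetry (construction is
#'   deterministic).
#' @return a [CorticalMesh-class]
#' @export
tessellateCortex <- function(phantom, nVertices = 642, nRegions = 84L,
                             seed = 1L) {
  if (nVertices < 12) stop("nVertices must be >= 12")
  gm <- .shellRadii(phantom, "gm")
  rMid <- mean(gm)
  counts <- 12L
  level <- 0L
  while (counts < nVertices) { level <- level + 1L; counts <- counts * 4L - 6L }
  ico <- .icosphere(level)
  verts <- ico$vertices * rMid
  normals <- ico$vertices
  seeds <- .regionSeedDirections(nRegions)
  sim <- ico$vertices %*% t(seeds$dirs)
  region <- max.col(sim, ties.method = "first")
  new("CorticalMesh", vertices = verts, triangles = ico$triangles,
      normals = normals, region = as.integer(region),
      nRegions = as.integer(nRegions))
}

#' Generate a synthetic bi-hemispheric distance-dependent connectome
#'
#' Region centroids are area-uniform points on two hemispheric caps of a
#' sphere of radius `radiusMm`; weights decay exponentially with Euclidean
#' centroid distance, inter-hemispheric connections are scaled down, and
#' multiplicative log-normal jitter adds realistic weight dispersion.
#' Weights are symmetric with zero diagonal and are globally rescaled so
#' the mean row sum is 1; tract lengths equal the Euclidean distances.
#'
#' @param nRegions even number of regions (default 84).
#' @param decayMm exponential decay length of the weights, mm.
#' @param interhemisphericScale multiplier in (0,1] applied to
#'   cross-hemisphere weights (0 disconnects the hemispheres).
#' @param seed integer RNG seed; same seed gives a bit-identical result.
#' @param radiusMm sphere radius for the centroids, mm (default 74, the
#'   mid-GM radius of the default phantom).
#' @param jitterSd sdlog of the log-normal weight jitter.
#' @return a [Connectome-class]
#' @export
synthConnectome <- function(nRegions = 84L, decayMm = 40,
                            interhemisphericScale = 0.5, seed = 1L,
                            radiusMm = 74, jitterSd = 0.5) {
  if (nRegions %% 2L != 0L) stop("nRegions must be even")
  if (decayMm <= 0) stop("decayMm must be > 0")
  seeds <- .regionSeedDirections(nRegions)
  cen <- seeds$dirs * radiusMm
  d <- as.matrix(stats::dist(cen))
  set.seed(as.integer(seed))
  jit <- matrix(0, nRegions, nRegions)
  ut <- upper.tri(jit)
  jit[ut] <- stats::rlnorm(sum(ut), meanlog = 0, sdlog = jitterSd)
  jit <- jit + t(jit)
  cross <- outer(seeds$hemisphere, seeds$hemisphere, "!=")
  w <- exp(-d / decayMm) * ifelse(cross, interhemisphericScale, 1) * jit
  diag(w) <- 0
  rs <- mean(rowSums(w))
  if (rs > 0) w <- w / rs
  m <- nRegions / 2L
  nm <- c(sprintf("L%02d", seq_len(m)), sprintf("R%02d", seq_len(m)))
  dimnames(w) <- dimnames(d) <- list(nm, nm)
  new("Connectome", weights = w, lengths = d, centroids = cen,
      names = nm, hemisphere = seeds$hemisphere)
}
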