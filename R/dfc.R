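# dfc_analysis: sliding-window functional connectivity, k-means state
# identification, PCA projection and occupancy/fluidity statistics.

#' Sliding-window functional connectivity
#'
#' Pearson correlation matrices over sliding windows of `windowSec`
#' seconds with the given overlap; window count is
#' floor((T - L) / (L (1 - overlap))) + 1.
#'
#' @param signals nodes x time matrix (e.g. [pyramidalPotential()]) or a
#'   [SimOutput-class].
#' @param fs sampling rate, Hz (taken from the SimOutput if given).
#' @param windowSec window length, s (default 10).
#' @param overlap overlap fraction (default 0.5).
#' @return a [DFCSeries-class]
#' @export
slidingFC <- function(signals, fs = NULL, windowSec = 10, overlap = 0.5) {
  if (is(signals, "SimOutput")) { fs <- signals@fs; signals <- signals@vpyr }
  if (is.null(fs)) stop("fs required for matrix input")
  n <- nrow(signals)
  nt <- ncol(signals)
  L <- round(windowSec * fs)
  if (L < 2) stop("window too short: fewer than 2 samples")
  step <- max(1, round(L * (1 - overlap)))
  nw <- floor((nt - L) / step) + 1
  if (nw < 1) stop("signal shorter than one window")
  fc <- array(0, c(n, n, nw))
  vecs <- matrix(0, nw, n * (n - 1) / 2)
  ut <- upper.tri(matrix(0, n, n))
  centers <- numeric(nw)
  for (w in seq_len(nw)) {
    i0 <- (w - 1) * step + 1
    blk <- signals[, i0:(i0 + L - 1), drop = FALSE]
    sds <- apply(blk, 1, sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1]
      stop(sprintf("node %d has zero variance in window %d; constant signals carry no FC",
                   bad, w))
    }
    cm <- cor(t(blk))
    fc[, , w] <- cm
    vecs[w, ] <- cm[ut]
    centers[w] <- (i0 - 1 + L / 2) / fs
  }
  new("DFCSeries", centers = centers, windowSec = windowSec,
      overlap = overlap, fc = fc, vectors = vecs)
}

#' K-means DFC state identification
#'
#' Clusters the upper-triangle FC vectors with seeded multi-restart
#' k-means (best inertia kept) and attaches occupancy, dwell-time and
#' transition-rate statistics.
#'
#' @param dfc a [DFCSeries-class].
#' @param k number of states.
#' @param seed integer RNG seed.
#' @param nInit random restarts (default 10).
#' @return a [StateModel-class]
#' @export
clusterStates <- function(dfc, k, seed = 1L, nInit = 10L) {
  set.seed(as.integer(seed))
  v <- dfc@vectors
  km <- if (k == 1L)
    list(cluster = rep(1L, nrow(v)), centers = matrix(colMeans(v), 1))
  else kmeans(v, centers = k, nstart = nInit, iter.max = 100L)
  labels <- as.integer(km$cluster)
  st <- stateStatistics(labels, stepSec = dfc@windowSec * (1 - dfc@overlap),
                        k = k)
  new("StateModel", k = as.integer(k), centers = km$centers,
      stateLabels = labels, occupancy = st$occupancy,
      meanDwell = st$meanDwell, transitionRate = st$transitionRate,
      pca = list())
}

#' Occupancy, dwell-time and transition statistics of a label sequence
#'
#' The transition rate (state changes per second of covered time) is the
#' package's fluidity proxy.
#'
#' @param labels integer state labels per window.
#' @param stepSec time between consecutive windows, s.
#' @param k number of states (default max label).
#' @return list(occupancy, meanDwell, transitionRate, nTransitions)
#' @export
stateStatistics <- function(labels, stepSec, k = max(labels)) {
  nw <- length(labels)
  occupancy <- tabulate(labels, nbins = k) / nw
  changes <- sum(diff(labels) != 0)
  span <- (nw - 1) * stepSec
  rate <- if (span > 0) changes / span else 0
  runs <- rle(labels)
  meanDwell <- mean(runs$lengths) * stepSec
  list(occupancy = occupancy, meanDwell = meanDwell,
       transitionRate = rate, nTransitions = changes)
}

#' PCA projection of a DFC series
#'
#' Mean-centred PCA of the FC vectors; component loadings can be
#' reshaped back to symmetric matrices with [pcLoadingMatrix()] for
#' display against the connectome block structure.
#'
#' @param dfc a [DFCSeries-class].
#' @param nComponents components to keep (default 2).
#' @param model optional [StateModel-class] to attach the projection to.
#' @return a [StateModel-class] with the `pca` slot filled (a trivial
#'   single-state model if none was given).
#' @export
pcaProject <- function(dfc, nComponents = 2, model = NULL) {
  v <- dfc@vectors
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$rotation))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- list(rotation = pc$rotation[, seq_len(nc), drop = FALSE],
              sdev = pc$sdev, scores = pc$x[, seq_len(nc), drop = FALSE],
              explained = expl)
  if (is.null(model)) {
    nw <- nrow(v)
    model <- new("StateModel", k = 1L, centers = matrix(colMeans(v), 1),
                 stateLabels = rep(1L, nw), occupancy = 1,
                 meanDwell = nw * dfc@windowSec * (1 - dfc@overlap),
                 transitionRate = 0, pca = pca)
  } else {
    model@pca <- pca
  }
  model
}

#' Reshape a PC loading vector to a symmetric FC-space matrix
#'
#' @param loading upper-triangle loading vector (one PCA rotation column).
#' @param n node count.
#' @return n x n symmetric matrix with zero diagonal.
#' @export
pcLoadingMatrix <- function(loading, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- loading
  m + t(m)
}

#' DFC fluidity measures
#'
#' Primary: state-transition rate per second (from the clustered label
#' sequence). Secondary: the variance of the pairwise correlations
#' between window FC vectors (dispersion of the FC landscape).
#'
#' @param model a [StateModel-class].
#' @param dfc the matching [DFCSeries-class].
#' @return list(transitionRate, fcVariance)
#' @export
dfcFluidity <- function(model, dfc) {
  cc <- cor(t(dfc@vectors))
  offd <- cc[upper.tri(cc)]
  list(transitionRate = model@transitionRate,
       fcVariance = stats::var(offd))
}

#' Mean silhouette score of a clustering (helper for choosing k)
#'
#' @param dfc a [DFCSeries-class].
#' @param model a [StateModel-class].
#' @return mean silhouette width over windows.
#' @export
silhouetteScore <- function(dfc, model) {
  v <- dfc@vectors
  lab <- model@stateLabels
  if (length(unique(lab)) < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(v))
  n <- nrow(v)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    ai <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    bi <- min(vapply(setdiff(unique(lab), lab[i]),
                     function(q) mean(d[i, lab == q]), numeric(1)),
              na.rm = TRUE)
    s[i] <- if (max(ai, bi) > 0) (bi - ai) / max(ai, bi) else 0
  }
  mean(s)
}
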