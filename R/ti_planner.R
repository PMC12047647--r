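# ti_planner: temporal-interference exposure metrics and multi-goal
# electrode/current optimization.

#' Modulation envelope magnitude (closed form)
#'
#' For two channel fields e1, e2 at a point, the tTIS quantity of
#' interest is the largest (over spatial directions n) amplitude of the
#' low-frequency envelope modulation of
#' sin(w1 t) e1.n + sin(w2 t) e2.n, which equals max_n 2 min(|e1.n|,
#' |e2.n|). With |e1| >= |e2| (after relabeling) and e2 flipped when the
#' angle between the fields is obtuse (the MEM is sign-invariant), the
#' closed form is 2|e2| when |e2| <= |e1| cos(angle), else
#' 2 |e2 x (e1 - e2)| / |e1 - e2|.
#'
#' @param e1,e2 numeric(3) channel field vectors, V/m.
#' @return scalar MEM, V/m.
#' @examples
#' memClosedForm(c(1, 0, 0), c(1, 0, 0))   # 2
#' memClosedForm(c(1, 0, 0), c(0, 0, 0))   # 0
#' @export
memClosedForm <- function(e1, e2) {
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) return(0)
  if (n2 > n1) { tmp <- e1; e1 <- e2; e2 <- tmp; tmp <- n1; n1 <- n2; n2 <- tmp }
  if (sum(e1 * e2) < 0) e2 <- -e2
  cosA <- sum(e1 * e2) / (n1 * n2)
  cosA <- max(-1, min(1, cosA))
  if (n2 <= n1 * cosA) return(2 * n2)
  d <- e1 - e2
  cr <- c(e2[2] * d[3] - e2[3] * d[2],
          e2[3] * d[1] - e2[1] * d[3],
          e2[1] * d[2] - e2[2] * d[1])
  2 * sqrt(sum(cr^2)) / sqrt(sum(d^2))
}

# vectorized closed form over n x 3 matrices (used for whole volumes)
.memVec <- function(E1, E2) {
  n1 <- sqrt(rowSums(E1^2)); n2 <- sqrt(rowSums(E2^2))
  swap <- n2 > n1
  if (any(swap)) {
    tmp <- E1[swap, , drop = FALSE]
    E1[swap, ] <- E2[swap, , drop = FALSE]
    E2[swap, ] <- tmp
    tmp <- n1[swap]; n1[swap] <- n2[swap]; n2[swap] <- tmp
  }
  dotp <- rowSums(E1 * E2)
  flip <- dotp < 0
  if (any(flip)) { E2[flip, ] <- -E2[flip, , drop = FALSE]; dotp[flip] <- -dotp[flip] }
  out <- numeric(length(n1))
  nz <- n1 > 0 & n2 > 0
  cosA <- ifelse(nz, pmax(-1, pmin(1, dotp / (n1 * n2))), 0)
  small <- nz & (n2 <= n1 * cosA)
  out[small] <- 2 * n2[small]
  big <- nz & !small
  if (any(big)) {
    D <- E1[big, , drop = FALSE] - E2[big, , drop = FALSE]
    E2b <- E2[big, , drop = FALSE]
    cr1 <- E2b[, 2] * D[, 3] - E2b[, 3] * D[, 2]
    cr2 <- E2b[, 3] * D[, 1] - E2b[, 1] * D[, 3]
    cr3 <- E2b[, 1] * D[, 2] - E2b[, 2] * D[, 1]
    out[big] <- 2 * sqrt(cr1^2 + cr2^2 + cr3^2) / sqrt(rowSums(D^2))
  }
  out
}

# Fibonacci-lattice unit directions
.fibonacciDirections <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  s <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (k - 1) * golden
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Modulation envelope magnitude (brute-force oracle)
#'
#' Independent verification of [memClosedForm()]: samples unit directions
#' on a Fibonacci lattice and, per direction, extracts the envelope of
#' the two-tone signal by time sampling (amplitude per carrier
#' half-period across one beat period); the per-direction modulation
#' magnitude is max - min envelope amplitude, and the MEM is the maximum
#' over directions.
#'
#' Per direction, the two projected tones a sin(w1 t) + b sin(w2 t) form a
#' slowly rotating phasor pair whose instantaneous amplitude at beat phase
#' phi is sqrt(a^2 + b^2 + 2 a b cos(phi)); the envelope modulation
#' magnitude is the max minus min of that amplitude over a dense grid of
#' beat phases. The maximum over directions is located on a Fibonacci
#' lattice and polished by Nelder-Mead on the sphere.
#'
#' @param e1,e2 numeric(3) channel fields, V/m.
#' @param nDirections unit directions sampled.
#' @param nPhases beat-phase samples per direction.
#' @param refine polish the best lattice direction with a local search.
#' @return scalar MEM, V/m.
#' @export
memBruteForce <- function(e1, e2, nDirections = 10000, nPhases = 1024,
                          refine = TRUE) {
  dirs <- .fibonacciDirections(nDirections)
  phi <- seq(0, pi, length.out = nPhases)
  cphi <- cos(phi)
  envMod <- function(a, b) {
    amp <- sqrt(pmax(0, a^2 + b^2 + 2 * a * b * cphi))
    max(amp) - min(amp)
  }
  a <- as.numeric(dirs %*% e1)
  b <- as.numeric(dirs %*% e2)
  # scan: envelope range on a coarse phase grid, vectorized over directions
  coarse <- cphi[seq(1, nPhases, length.out = min(64, nPhases))]
  sq <- a^2 + b^2
  ab2 <- 2 * a * b
  hi <- rep(-Inf, nDirections); lo <- rep(Inf, nDirections)
  for (cp in coarse) {
    amp <- sqrt(pmax(0, sq + ab2 * cp))
    hi <- pmax(hi, amp); lo <- pmin(lo, amp)
  }
  vals <- hi - lo
  best <- which.max(vals)
  out <- envMod(a[best], b[best])
  if (refine) {
    # polish up to three angularly distinct lattice candidates
    ord <- order(vals, decreasing = TRUE)
    cand <- ord[1]
    for (k in ord) {
      if (length(cand) >= 3) break
      if (all(abs(dirs[k, ] %*% t(dirs[cand, , drop = FALSE])) < cos(0.25)))
        cand <- c(cand, k)
    }
    f <- function(p) {
      n <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
      -envMod(sum(n * e1), sum(n * e2))
    }
    for (ci in cand) {
      d0 <- dirs[ci, ]
      th0 <- acos(max(-1, min(1, d0[3])))
      ph0 <- atan2(d0[2], d0[1])
      op <- stats::optim(c(th0, ph0), f, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 400))
      out <- max(out, -op$value)
    }
  }
  out
}

#' Per-voxel exposure map of a stimulation configuration
#'
#' Channel fields are assembled from the unit-current basis by
#' superposition and scaled by the channel currents; the map is the MEM
#' (tTIS) or the field magnitude |E| (tACS, single-channel).
#'
#' @param basis an [EFieldBasis-class].
#' @param config a [StimConfig-class].
#' @param quantity "MEM" (default for two channels) or "|E|".
#' @return 3D array over the grid (0 outside the conducting domain),
#'   V/m; attribute "qoi" records the quantity.
#' @export
exposureMap <- function(basis, config, quantity = NULL) {
  tacs <- length(config@pair2) != 2L
  if (is.null(quantity)) quantity <- if (tacs) "|E|" else "MEM"
  dims <- dim(basis@mask)
  nv <- prod(dims)
  f1 <- basisField(basis, config@pair1[1], config@pair1[2]) * config@current1
  E1 <- matrix(f1, nv, 3)
  if (quantity == "|E|") {
    q <- sqrt(rowSums(E1^2))
  } else {
    if (tacs) stop("MEM needs two channels")
    f2 <- basisField(basis, config@pair2[1], config@pair2[2]) * config@current2
    E2 <- matrix(f2, nv, 3)
    q <- .memVec(E1, E2)
  }
  out <- array(q, dims)
  out[!basis@mask] <- 0
  attr(out, "qoi") <- quantity
  out
}

#' Exposure performance metrics M1-M3
#'
#' M1 (strength): p-th linear-interpolation percentile of the QoI over
#' the target; M2 (selectivity): mean target QoI / mean off-target
#' (non-target brain) QoI; M3 (collateral): fraction of non-target brain
#' voxels with QoI above the threshold (by default the configuration's
#' own M1).
#'
#' @param qoi 3D exposure map (e.g. from [exposureMap()]).
#' @param targetMask,brainMask logical arrays; target must be inside brain.
#' @param p percentile for M1 (default 50, the median).
#' @param threshold "auto" (the configuration's own M1) or a number, V/m.
#' @return an [ExposureMetrics-class]
#' @export
exposureMetrics <- function(qoi, targetMask, brainMask, p = 50,
                            threshold = "auto") {
  if (!any(targetMask) || !any(brainMask)) stop("empty target or brain mask")
  if (any(targetMask & !brainMask)) stop("target must be a subset of brain")
  off <- brainMask & !targetMask
  if (!any(off)) stop("no off-target brain voxels")
  tv <- qoi[targetMask]
  ov <- qoi[off]
  m1 <- as.numeric(quantile(tv, p / 100, type = 7))
  mo <- mean(ov)
  m2 <- if (mo == 0) {
    warning("mean off-target QoI is zero; selectivity undefined (+Inf)")
    Inf
  } else mean(tv) / mo
  thr <- if (identical(threshold, "auto")) m1 else as.numeric(threshold)
  m3 <- mean(ov > thr)
  new("ExposureMetrics", m1 = m1, m2 = m2, m3 = m3, p = p, threshold = thr,
      qoi = attr(qoi, "qoi") %||% "MEM")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate candidate tTIS configurations
#'
#' All unordered pairs of disjoint electrode pairs drawn from the
#' candidate set, crossed with a grid of current splits of the fixed
#' total (I1 = r * I, I2 = (1 - r) * I).
#'
#' @param electrodes character vector of candidate electrode labels, or a
#'   list of candidate pairs (character(2) each).
#' @param totalCurrent total current, mA.
#' @param ratios current-split grid (should include 0.5).
#' @param freqs numeric(2) channel frequencies, Hz.
#' @return list of [StimConfig-class]
#' @export
enumerateConfigs <- function(electrodes, totalCurrent = 2, ratios = 0.5,
                             freqs = c(2000, 2070)) {
  if (is.list(electrodes)) {
    pairs <- electrodes
  } else {
    cmb <- utils::combn(electrodes, 2, simplify = FALSE)
    pairs <- cmb
  }
  np <- length(pairs)
  configs <- list()
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    if (length(intersect(pairs[[i]], pairs[[j]]))) next
    for (r in ratios) {
      configs[[length(configs) + 1L]] <-
        new("StimConfig", pair1 = pairs[[i]], pair2 = pairs[[j]],
            current1 = r * totalCurrent, current2 = (1 - r) * totalCurrent,
            freq1 = freqs[1], freq2 = freqs[2])
    }
  }
  configs
}

# dominance matrix check: maximize m1, m2; minimize m3
.paretoFlags <- function(m) {
  n <- nrow(m)
  flags <- rep(TRUE, n)
  s <- cbind(m[, 1], m[, 2], -m[, 3])     # all maximized
  for (i in seq_len(n)) {
    geq <- s[, 1] >= s[i, 1] & s[, 2] >= s[i, 2] & s[, 3] >= s[i, 3]
    gt <- s[, 1] > s[i, 1] | s[, 2] > s[i, 2] | s[, 3] > s[i, 3]
    if (any(geq & gt)) flags[i] <- FALSE
  }
  flags
}

#' Pareto-optimal front of a configuration set
#'
#' A configuration is dominated iff another is at least as good on all
#' three objectives (maximize M1 and M2, minimize M3) and strictly
#' better on at least one; identical metric triples all stay on the
#' front.
#'
#' @param metrics list of [ExposureMetrics-class] (or a 3-column matrix
#'   m1, m2, m3).
#' @param configs optional list of [StimConfig-class] in the same order.
#' @return a [ParetoResult-class] with an unweighted ranking (front
#'   first, input order within groups).
#' @export
paretoFront <- function(metrics, configs = list()) {
  m <- if (is.matrix(metrics)) metrics else
    t(vapply(metrics, function(x) c(x@m1, x@m2, x@m3), numeric(3)))
  colnames(m) <- c("m1", "m2", "m3")
  flags <- .paretoFlags(m)
  tab <- data.frame(m, pareto = flags, score = NA_real_)
  tab$rank <- order(order(!tab$pareto, seq_len(nrow(tab))))
  new("ParetoResult", table = tab, configs = configs,
      weights = rep(NA_real_, 3))
}

#' Weighted ranking over a Pareto result
#'
#' Score = w1 norm(m1) + w2 norm(m2) + w3 norm(-m3) with min-max
#' normalization over the candidate set; configurations are sorted by
#' descending score with a stable input-order tie-break, and Pareto
#' members always precede dominated ones regardless of score.
#'
#' @param result a [ParetoResult-class].
#' @param weights numeric(3) nonnegative objective weights.
#' @return the [ParetoResult-class] with `score` and `rank` updated.
#' @export
weightedRank <- function(result, weights = c(1, 1, 1)) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  tab <- result@table
  norm01 <- function(x) {
    rng <- range(x[is.finite(x)])
    if (diff(rng) == 0) return(rep(0.5, length(x)))
    out <- (x - rng[1]) / diff(rng)
    out[!is.finite(x) & x > 0] <- 1
    out[!is.finite(x) & x < 0] <- 0
    out
  }
  score <- weights[1] * norm01(tab$m1) + weights[2] * norm01(tab$m2) +
    weights[3] * norm01(-tab$m3)
  tab$score <- score
  ord <- order(!tab$pareto, -score, seq_len(nrow(tab)))
  tab$rank <- order(ord)
  new("ParetoResult", table = tab, configs = result@configs,
      weights = weights)
}

#' Ranked configuration report
#'
#' @param result a ranked [ParetoResult-class].
#' @return data.frame sorted by rank, with configuration descriptors.
#' @export
rankedConfigTable <- function(result) {
  tab <- result@table
  if (length(result@configs) == nrow(tab)) {
    desc <- vapply(result@configs, function(cf) {
      if (length(cf@pair2) == 2L)
        sprintf("%s-%s %.2gmA | %s-%s %.2gmA", cf@pair1[1], cf@pair1[2],
                cf@current1, cf@pair2[1], cf@pair2[2], cf@current2)
      else sprintf("%s-%s %.2gmA", cf@pair1[1], cf@pair1[2], cf@current1)
    }, character(1))
    tab$config <- desc
  }
  tab[order(tab$rank), ]
}

#' Personalized current steering over a fixed electrode-pair choice
#'
#' Sweeps the current-split grid for fixed channel pairs (total current
#' held constant), scores each split with [weightedRank()] over the sweep
#' set, and returns the best configuration; by construction the winner
#' never scores below the 50/50 split (0.5 is always added to the grid).
#'
#' @param basis an [EFieldBasis-class].
#' @param pair1,pair2 character(2) channel electrode pairs.
#' @param targetMask,brainMask masks for [exposureMetrics()].
#' @param totalCurrent total current, mA.
#' @param ratios split grid.
#' @param weights objective weights.
#' @param freqs channel frequencies, Hz.
#' @param p,threshold metric settings.
#' @return list(config, metrics, ratio, sweep) where sweep is the ranked
#'   table over the grid.
#' @export
steerCurrents <- function(basis, pair1, pair2, targetMask, brainMask,
                          totalCurrent = 2, ratios = seq(0.1, 0.9, by = 0.1),
                          weights = c(1, 1, 1), freqs = c(2000, 2070),
                          p = 50, threshold = "auto") {
  ratios <- sort(unique(c(ratios, 0.5)))
  configs <- lapply(ratios, function(r)
    new("StimConfig", pair1 = pair1, pair2 = pair2,
        current1 = r * totalCurrent, current2 = (1 - r) * totalCurrent,
        freq1 = freqs[1], freq2 = freqs[2]))
  mets <- lapply(configs, function(cf)
    exposureMetrics(exposureMap(basis, cf), targetMask, brainMask,
                    p = p, threshold = threshold))
  pr <- weightedRank(paretoFront(mets, configs), weights)
  tab <- pr@table
  tab$ratio <- ratios
  best <- which(tab$rank == 1)
  list(config = configs[[best]], metrics = mets[[best]],
       ratio = ratios[best], sweep = tab)
}
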