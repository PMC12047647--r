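# Jansen-Rit network: sigmoid, coupling geometry, integration accuracy,
# dynamical regimes, stimulus coupling

test_that("sigmoid hits its midpoint, saturation and monotonicity", {
  p <- jrParams()
  expect_equal(jrSigmoid(p$v0, p), 2.5)
  expect_equal(jrSigmoid(1e4, p), 5, tolerance = 1e-12)
  expect_equal(jrSigmoid(-1e4, p), 0, tolerance = 1e-12)
  v <- sort(rnorm(50, sd = 10))
  expect_true(all(diff(jrSigmoid(v, p)) > 0))
})

test_that("network construction: local kernel values, cutoff, delays", {
  ph <- coarsePhantom()
  mesh <- tessellateCortex(ph, 642, nRegions = 8L)   # ~10 mm vertex spacing
  con <- synthConnectome(8L, seed = 2, radiusMm = 70)
  # width 10 mm: two nodes 10 mm apart couple at amplitude exp(-1/2)
  params <- jrParams()
  net <- buildNetworkModel(con, mesh, "surface", params)
  pos <- net@positions
  rad <- sqrt(rowSums(pos^2)); R <- mean(rad)
  cosang <- tcrossprod(pos / rad)
  d <- R * acos(pmin(pmax(cosang, -1), 1))
  L <- as.matrix(net@localW)
  off <- which(upper.tri(d) & d > 1 & d < 19, arr.ind = TRUE)
  i <- off[1, 1]; j <- off[1, 2]
  expect_equal(L[i, j], exp(-d[i, j]^2 / 200), tolerance = 1e-9)
  expect_true(all(L[d > 20] == 0))
  expect_true(all(diag(L) == 0))
  # cutoff 0 kills the whole local matrix
  net0 <- buildNetworkModel(con, mesh, "surface", jrParams(localCutoff = 0))
  expect_equal(Matrix::nnzero(net0@localW), 0)
  # delay arithmetic: 60 mm at 3 mm/ms with dt 0.5 ms -> 40 steps
  netR <- buildNetworkModel(con, mode = "region")
  netR@lengths[1, 2] <- 60
  expect_equal(delaySteps(netR, 5e-4, speed = 3)[1, 2], 40)
})

test_that("noise-free uncoupled node settles onto the algebraic fixed point", {
  params <- jrParams(noiseSigma = 0, pMean = 0, G = 0)
  sim <- simulateNetwork(singleNode(), params, duration = 5, burnin = 4,
                         seed = 1)
  vEnd <- tail(pyramidalPotential(sim)[1, ], 1)
  # independent oracle: residual of the six stationary equations at vEnd
  S <- function(v) 2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
  y0 <- params$A / params$a * S(vEnd)
  y1 <- params$A / params$a * (0 + params$C2 * S(params$C1 * y0))
  y2 <- params$B / params$b * params$C4 * S(params$C3 * y0)
  expect_lt(abs((y1 - y2) - vEnd), 1e-6)
  # and the packaged root finder agrees
  expect_equal(vEnd, jrFixedPoint(params, 0)$v, tolerance = 1e-6)
})

test_that("fluid regime (a=60, b=30) oscillates where the defaults decay", {
  probeInput <- 100                        # constant mid-range pulse density
  tailSd <- function(params) {
    sim <- simulateNetwork(singleNode(),
                           params, duration = 11, burnin = 1, seed = 1)
    v <- pyramidalPotential(sim)[1, ]
    sd(tail(v, 4000))
  }
  sdDefault <- tailSd(jrParams(noiseSigma = 0, pMean = probeInput, G = 0))
  sdFluid <- tailSd(jrParams(a = 60, b = 30, noiseSigma = 0,
                             pMean = probeInput, G = 0))
  expect_lt(sdDefault, 1e-3)               # decays to the fixed point
  expect_gt(sdFluid, 1)                    # sustained limit cycle
})

test_that("single noisy node expresses an alpha-band spectral peak", {
  sim <- simulateNetwork(singleNode(), jrParams(G = 0), duration = 21,
                         burnin = 1, seed = 2)
  sp <- psdWelch(pyramidalPotential(sim), fs = sim@fs, windowSec = 2)
  pk <- psdPeakFrequency(sp)
  expect_gte(pk, 8)
  expect_lte(pk, 12)
})

test_that("dt-halving changes the average log-PSD by under 5% (convergence)", {
  # noise-free: isolates the integrator's discretization error (the
  # default noise intensity adds a microscopic stochastic floor whose
  # realization differs between step counts)
  run <- function(dt) {
    sim <- simulateNetwork(singleNode(), jrParams(G = 0, noiseSigma = 0),
                           duration = 31, burnin = 1, dt = dt, seed = 3)
    psdWelch(pyramidalPotential(sim), fs = sim@fs, windowSec = 2)
  }
  s1 <- run(5e-4); s2 <- run(2.5e-4)
  band <- s1@freq >= 1 & s1@freq <= 40
  f <- s1@freq[band]
  p1 <- log10(s1@channelMean[band])
  p2 <- log10(s2@channelMean[match(f, s2@freq)])
  rel <- sqrt(mean((p1 - p2)^2)) / sqrt(mean((p1 - mean(p1))^2))
  expect_lt(rel, 0.05)
})

test_that("seeding: identical seeds reproduce; zero-amplitude drive is a no-op", {
  con <- synthConnectome(8L, seed = 4)
  net <- buildNetworkModel(con, mode = "region")
  s1 <- simulateNetwork(net, jrParams(), duration = 3, burnin = 1, seed = 7)
  s2 <- simulateNetwork(net, jrParams(), duration = 3, burnin = 1, seed = 7)
  expect_identical(pyramidalPotential(s1), pyramidalPotential(s2))
  drv0 <- new("StimulusDrive", amplitude = numeric(8), freqHz = 10,
              window = c(0, 10), shape = "sinusoid")
  s3 <- simulateNetwork(net, jrParams(), drive = drv0, duration = 3,
                        burnin = 1, seed = 7)
  expect_identical(pyramidalPotential(s1), pyramidalPotential(s3))
  # different seeds: same spectral peak location within one PSD bin
  long1 <- simulateNetwork(net, jrParams(), duration = 11, burnin = 1,
                           seed = 1)
  long2 <- simulateNetwork(net, jrParams(), duration = 11, burnin = 1,
                           seed = 99)
  f1 <- psdPeakFrequency(psdWelch(pyramidalPotential(long1), fs = long1@fs))
  f2 <- psdPeakFrequency(psdWelch(pyramidalPotential(long2), fs = long2@fs))
  expect_lte(abs(f1 - f2), 0.5)
})

test_that("stimulus drive amplitudes follow lambda (E.n) with sign symmetry", {
  net <- singleNode()
  ez <- matrix(c(0, 0, 1), 1)              # E parallel to the normal
  d1 <- makeStimulusDrive(ez, net, lambda = 1)
  expect_equal(d1@amplitude, 1)            # 1 V/m x 1 mm = 1 mV
  ex <- matrix(c(1, 0, 0), 1)              # E perpendicular to the normal
  expect_equal(makeStimulusDrive(ex, net)@amplitude, 0)
  netFlip <- net; netFlip@normals <- -net@normals
  expect_equal(makeStimulusDrive(ez, netFlip, lambda = 2)@amplitude, -2)
})

test_that("spectral response at the drive frequency grows with lambda", {
  con <- synthConnectome(8L, seed = 4)
  net <- buildNetworkModel(con, mode = "region")
  fDrive <- 6
  base <- simulateNetwork(net, jrParams(), duration = 13, burnin = 1,
                          seed = 5)
  bp <- psdWelch(pyramidalPotential(base), fs = base@fs, windowSec = 2)
  atDrive <- function(sp) sp@channelMean[which.min(abs(sp@freq - fDrive))]
  gains <- vapply(c(0.5, 2, 8), function(lam) {
    # uniform unit normal-component field scaled by lambda
    drv <- makeStimulusDrive(net@normals, net, lambda = lam,
                             freqHz = fDrive, window = c(0, 13))
    sim <- simulateNetwork(net, jrParams(), drive = drv, duration = 13,
                           burnin = 1, seed = 5)
    atDrive(psdWelch(pyramidalPotential(sim), fs = sim@fs, windowSec = 2)) -
      atDrive(bp)
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("NaN states abort with the offending step", {
  net <- singleNode()
  bad <- jrParams(a = 1e6, noiseSigma = 0)   # far beyond the stability limit
  expect_error(simulateNetwork(net, bad, duration = 2, burnin = 1, seed = 1),
               "non-finite")
})
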