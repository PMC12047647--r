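# temporal-interference planning: MEM, exposure metrics, Pareto, steering

test_that("MEM closed form: analytic cases", {
  expect_equal(memClosedForm(c(1, 0, 0), c(1, 0, 0)), 2)
  expect_equal(memClosedForm(c(1, 0, 0), c(0, 0, 0)), 0)
  expect_equal(memClosedForm(c(1, 0, 0), c(-1, 0, 0)), 2)
  expect_equal(memClosedForm(c(1, 0, 0), c(0, 1, 0)), sqrt(2),
               tolerance = 1e-12)
})

test_that("MEM closed form matches the brute-force oracle (seeded pairs)", {
  set.seed(123)
  for (i in 1:60) {
    e1 <- rnorm(3); e2 <- rnorm(3)
    cf <- memClosedForm(e1, e2)
    bf <- memBruteForce(e1, e2, nDirections = 4000)
    expect_lt(abs(cf - bf) / max(cf, 1e-12), 1e-3)
  }
  # parallel case and monotonicity of the oracle in |e2|
  expect_equal(memBruteForce(c(2, 0, 0), c(1, 0, 0), nDirections = 500), 2,
               tolerance = 1e-9)
  vals <- vapply(c(0.2, 0.5, 0.8), function(s)
    memBruteForce(c(1, 0, 0), c(0, s, 0), nDirections = 2000), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("MEM symmetries and the 2 min(|e1|,|e2|) bound (property)", {
  set.seed(11)
  for (i in 1:200) {
    e1 <- rnorm(3); e2 <- rnorm(3)
    m <- memClosedForm(e1, e2)
    expect_equal(m, memClosedForm(e2, e1), tolerance = 1e-12)
    expect_equal(m, memClosedForm(-e1, e2), tolerance = 1e-12)
    expect_lte(m, 2 * min(sqrt(sum(e1^2)), sqrt(sum(e2^2))) + 1e-12)
  }
  # vectorized form agrees with the scalar form
  E1 <- matrix(rnorm(60), 20); E2 <- matrix(rnorm(60), 20)
  v <- nibsim:::.memVec(E1, E2)
  s <- vapply(1:20, function(i) memClosedForm(E1[i, ], E2[i, ]), numeric(1))
  expect_equal(v, s, tolerance = 1e-12)
})

# tiny synthetic basis: 3 "electrodes" with hand-made fields on a 6^3 grid
syntheticBasis <- function() {
  dims <- c(6L, 6L, 6L)
  mask <- array(TRUE, dims)
  mk <- function(vx, vy, vz) {
    f <- array(0, c(dims, 3))
    f[, , , 1] <- vx; f[, , , 2] <- vy; f[, , , 3] <- vz
    f
  }
  set.seed(20)
  fields <- list(A = mk(1, 0, 0) + array(rnorm(prod(dims) * 3, sd = 0.1),
                                         c(dims, 3)),
                 B = mk(0, 1, 0) + array(rnorm(prod(dims) * 3, sd = 0.1),
                                         c(dims, 3)),
                 C = mk(0.5, 0.5, 0) + array(rnorm(prod(dims) * 3, sd = 0.1),
                                             c(dims, 3)))
  new("EFieldBasis", fields = fields, reference = "R", mask = mask,
      spacing = rep(2, 3), origin = c(0, 0, 0), meta = list())
}

test_that("exposure map: homogeneity, channel swap, silent channel", {
  basis <- syntheticBasis()
  cfg <- new("StimConfig", pair1 = c("A", "R"), pair2 = c("B", "C"),
             current1 = 1, current2 = 1, freq1 = 2000, freq2 = 2070)
  m1 <- exposureMap(basis, cfg)
  cfg2 <- cfg; cfg2@current1 <- 2; cfg2@current2 <- 2
  expect_equal(exposureMap(basis, cfg2), 2 * m1, tolerance = 1e-12,
               ignore_attr = TRUE)
  swap <- new("StimConfig", pair1 = c("B", "C"), pair2 = c("A", "R"),
              current1 = 1, current2 = 1, freq1 = 2000, freq2 = 2070)
  expect_equal(exposureMap(basis, swap), m1, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a zero channel-2 field kills the interference everywhere
  basis0 <- basis
  basis0@fields$B <- basis0@fields$C       # B - C = 0 pair field
  cfg0 <- new("StimConfig", pair1 = c("A", "R"), pair2 = c("B", "C"),
              current1 = 1, current2 = 1, freq1 = 2000, freq2 = 2070)
  expect_equal(max(exposureMap(basis0, cfg0)), 0)
  expect_error(exposureMap(basis, new("StimConfig", pair1 = c("Z", "R"),
                                      pair2 = c("B", "C"), current1 = 1,
                                      current2 = 1, freq1 = 2000,
                                      freq2 = 2070)), "not in basis")
})

test_that("exposure metrics M1-M3 match the worked examples", {
  qoi <- array(0, c(4, 2, 1))
  qoi[, 1, 1] <- c(1, 2, 3, 4)                # target
  qoi[, 2, 1] <- c(1, 3, 3, 5)                # off-target
  target <- array(FALSE, dim(qoi)); target[, 1, 1] <- TRUE
  brain <- array(TRUE, dim(qoi))
  m <- exposureMetrics(qoi, target, brain, p = 50, threshold = 2.5)
  expect_equal(m@m1, 2.5)                      # linear-interp median
  expect_equal(m@m2, mean(c(1, 2, 3, 4)) / mean(c(1, 3, 3, 5)))
  expect_equal(m@m3, 0.75)                     # 3 of 4 above 2.5
  # auto threshold uses the configuration's own m1
  mAuto <- exposureMetrics(qoi, target, brain, p = 50)
  expect_equal(mAuto@threshold, 2.5)
  # target mean 2 vs off-target mean 1
  q2 <- array(c(2, 2, 1, 1), c(4, 1, 1))
  t2 <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  expect_equal(exposureMetrics(q2, t2, array(TRUE, c(4, 1, 1)))@m2, 2)
  expect_error(exposureMetrics(qoi, array(FALSE, dim(qoi)), brain), "empty")
  expect_warning(
    m0 <- exposureMetrics(array(c(1, 0), c(2, 1, 1)),
                          array(c(TRUE, FALSE), c(2, 1, 1)),
                          array(TRUE, c(2, 1, 1))),
    "undefined")
  expect_equal(m0@m2, Inf)
})

test_that("metric scaling: QoI scaled by k scales m1, fixes m2 and auto-m3", {
  set.seed(9)
  qoi <- array(rexp(64), c(4, 4, 4))
  target <- array(FALSE, dim(qoi)); target[1:2, , ] <- TRUE
  brain <- array(TRUE, dim(qoi))
  a <- exposureMetrics(qoi, target, brain)
  b <- exposureMetrics(qoi * 3, target, brain)
  expect_equal(b@m1, 3 * a@m1)
  expect_equal(b@m2, a@m2)
  expect_equal(b@m3, a@m3)                     # auto threshold co-scales
})

test_that("configuration enumeration covers disjoint pair-of-pairs times ratios", {
  cfgs <- enumerateConfigs(c("a", "b", "c", "d"), ratios = 0.5)
  expect_length(cfgs, 3)                       # {ab|cd, ac|bd, ad|bc}
  for (cf in cfgs)
    expect_length(intersect(cf@pair1, cf@pair2), 0)
  cfg5 <- enumerateConfigs(c("a", "b", "c", "d"),
                           ratios = seq(0.1, 0.9, by = 0.2))
  expect_length(cfg5, 15)
})

test_that("pareto front equals the O(n^2) brute-force non-dominated set", {
  expect_equal(paretoFront(rbind(c(1, 1, 1), c(2, 2, 0.5)))@table$pareto,
               c(FALSE, TRUE))
  idt <- matrix(rep(c(1, 2, 0.3), each = 4), 4)
  expect_true(all(paretoFront(idt)@table$pareto))   # ties all kept
  set.seed(77)
  m <- cbind(runif(200), runif(200), runif(200))
  flags <- paretoFront(m)@table$pareto
  # independent double-loop oracle
  oracle <- rep(TRUE, 200)
  for (i in 1:200) for (j in 1:200) {
    if (i == j) next
    if (m[j, 1] >= m[i, 1] && m[j, 2] >= m[i, 2] && m[j, 3] <= m[i, 3] &&
        (m[j, 1] > m[i, 1] || m[j, 2] > m[i, 2] || m[j, 3] < m[i, 3])) {
      oracle[i] <- FALSE; break
    }
  }
  expect_identical(flags, oracle)
  # front of the front is the front (idempotence)
  front <- m[flags, ]
  expect_true(all(paretoFront(front)@table$pareto))
})

test_that("weighted ranking respects the front and the tie-break contract", {
  set.seed(31)
  m <- cbind(runif(50), runif(50), runif(50))
  pr <- paretoFront(m)
  for (w in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(0.2, 2, 0.7))) {
    rk <- weightedRank(pr, w)
    tab <- rk@table
    # no dominated config above any front member
    expect_lt(max(tab$rank[tab$pareto]), min(tab$rank[!tab$pareto]))
  }
  # w = (1,0,0): top rank has max m1 among the front
  rk <- weightedRank(pr, c(1, 0, 0))
  top <- which(rk@table$rank == 1)
  expect_equal(rk@table$m1[top], max(rk@table$m1[rk@table$pareto]))
  # identical metrics: stable order by input index
  same <- matrix(rep(c(1, 1, 1), each = 5), 5)
  rk2 <- weightedRank(paretoFront(same), c(1, 1, 1))
  expect_equal(rk2@table$rank, 1:5)
})

test_that("current steering never scores below the 50/50 split; symmetric optimum at 0.5", {
  ph <- coarsePhantom()
  mon <- placeElectrodes1010(ph)
  sig <- assignTissueConductivity(ph)
  basis <- computeFieldBasis(sig, ph, mon,
                             labels = c("P7", "AF7", "P8", "AF8"),
                             tol = 1e-8)
  target <- targetBallMask(ph, c(0, 0, 40), 15)
  brain <- brainMask(ph)
  st <- steerCurrents(basis, c("P7", "AF7"), c("P8", "AF8"), target, brain,
                      ratios = seq(0.1, 0.9, by = 0.1))
  tab <- st$sweep
  expect_gte(st$config@current1 + st$config@current2, 2 - 1e-9)
  expect_gte(tab$score[tab$ratio == st$ratio],
             tab$score[tab$ratio == 0.5] - 1e-12)
  # mirrored pairs + midline target: optimum within one grid step of 0.5
  expect_lte(abs(st$ratio - 0.5), 0.1 + 1e-9)
  # asymmetric target: the steered score still dominates the 50/50 score
  target2 <- targetBallMask(ph, c(30, 0, 30), 12)
  st2 <- steerCurrents(basis, c("P7", "AF7"), c("P8", "AF8"), target2, brain,
                       ratios = seq(0.1, 0.9, by = 0.1))
  expect_gte(st2$sweep$score[st2$sweep$ratio == st2$ratio],
             st2$sweep$score[st2$sweep$ratio == 0.5] - 1e-12)
})
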