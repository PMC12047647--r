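// Stochastic Heun (modified trapezoidal) integrator for Jansen-Rit
// neural-mass networks with delayed long-range coupling at region
// granularity, optional local (surface) coupling, and a lambda*E stimulus
// added to the pyramidal membrane potential wherever it enters a sigmoid.
//
// State per node: y0..y5 with
//   y0' = y3;  y3' = A a S(y1 - y2 + s) - 2 a y3 - a^2 y0
//   y1' = y4;  y4' = A a (p + C2 S(C1 y0) + cpl) - 2 a y4 - a^2 y1
//   y2' = y5;  y5' = B b C4 S(C3 y0) - 2 b y5 - b^2 y2
// cpl_i = G * sum_R Wreg(region(i), R) * Sbar_R(t - tau(region(i), R))
//         + sum_j L(i, j) * S(vpyr_j + s_j)      (local, undelayed)
// Additive noise (same Wiener increment in predictor and corrector)
// enters y4. Noise draws use R's RNG so runs are seed-reproducible.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static inline double sigm(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// [[Rcpp::export(name = ".jr_simulate")]]
Rcpp::List jr_simulate(const arma::mat& Wreg, const arma::imat& Dreg,
                       const arma::ivec& regionOf, const arma::sp_mat& L,
                       bool useLocal,
                       double A, double B, double a, double b,
                       double C1, double C2, double C3, double C4,
                       double v0, double e0, double r,
                       double G, double pmean, double noiseIncSd,
                       const arma::vec& stimAmp, int stimShape,
                       double stimFreq, double stimOn, double stimOff,
                       double dt, int nSteps, int burnSteps,
                       int recordEvery) {
  const int n = regionOf.n_elem;
  const int R = Wreg.n_rows;
  const bool haveStim = stimShape > 0;

  int maxDelay = Dreg.max();
  if (maxDelay < 0) Rcpp::stop("negative delay step");
  const int bufLen = maxDelay + 2;

  // region-size for Sbar aggregation
  arma::vec regCount(R, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    if (regionOf[i] < 0 || regionOf[i] >= R) Rcpp::stop("region index out of range");
    regCount[regionOf[i]] += 1.0;
  }
  for (int q = 0; q < R; ++q) if (regCount[q] == 0) regCount[q] = 1.0;

  arma::mat y(n, 6, arma::fill::zeros);
  arma::mat Sbuf(R, bufLen, arma::fill::zeros);

  const int nRec = (nSteps - burnSteps) / recordEvery;
  arma::mat out(n, nRec, arma::fill::zeros);
  arma::vec tout(nRec, arma::fill::zeros);

  arma::vec svec(n), sbar(R), cplLong(R), cpl(n), xi(n);
  arma::vec svecP(n), sbarP(R);
  arma::mat k1(n, 6), k2(n, 6), yp(n, 6);

  auto stimAt = [&](double t, int i) -> double {
    if (!haveStim) return 0.0;
    if (t < stimOn || t >= stimOff) return 0.0;
    double w;
    switch (stimShape) {
      case 1: w = std::sin(2.0 * M_PI * stimFreq * t); break;          // sinusoid
      case 2: w = 1.0; break;                                          // dc
      case 3: {                                                        // am (Hann)
        double u = (t - stimOn) / (stimOff - stimOn);
        w = std::sin(2.0 * M_PI * stimFreq * t) *
            0.5 * (1.0 - std::cos(2.0 * M_PI * u));
        break;
      }
      default: Rcpp::stop("unknown stimulus shape");
    }
    return stimAmp[i] * w;
  };

  auto deriv = [&](const arma::mat& yy, const arma::vec& sv,
                   const arma::vec& cp, double t, arma::mat& k) {
    for (int i = 0; i < n; ++i) {
      double y0 = yy(i, 0), y1 = yy(i, 1), y2 = yy(i, 2);
      double y3 = yy(i, 3), y4 = yy(i, 4), y5 = yy(i, 5);
      k(i, 0) = y3;
      k(i, 1) = y4;
      k(i, 2) = y5;
      k(i, 3) = A * a * sv[i] - 2.0 * a * y3 - a * a * y0;
      k(i, 4) = A * a * (pmean + C2 * sigm(C1 * y0, e0, r, v0) + cp[i])
                - 2.0 * a * y4 - a * a * y1;
      k(i, 5) = B * b * C4 * sigm(C3 * y0, e0, r, v0)
                - 2.0 * b * y5 - b * b * y2;
    }
    (void)t;
  };

  // prime the delay buffer with the initial transmitted rate
  {
    double s0 = sigm(0.0, e0, r, v0);
    Sbuf.fill(s0);
  }

  Rcpp::RNGScope scope;
  int rec = 0;
  for (int step = 0; step < nSteps; ++step) {
    double t = step * dt;
    // transmitted firing rate at time t (stimulus inside the sigmoid)
    for (int i = 0; i < n; ++i)
      svec[i] = sigm(y(i, 1) - y(i, 2) + stimAt(t, i), e0, r, v0);
    // region-average rate, write into ring buffer
    sbar.zeros();
    for (int i = 0; i < n; ++i) sbar[regionOf[i]] += svec[i];
    sbar /= regCount;
    int slot = step % bufLen;
    Sbuf.col(slot) = sbar;
    // delayed long-range coupling, region level
    for (int q = 0; q < R; ++q) {
      double acc = 0.0;
      for (int p2 = 0; p2 < R; ++p2) {
        double w = Wreg(q, p2);
        if (w == 0.0) continue;
        int d = Dreg(q, p2);
        int src = step - d;
        double sdel = (src < 0) ? sigm(0.0, e0, r, v0)
                                : Sbuf(p2, src % bufLen);
        acc += w * sdel;
      }
      cplLong[q] = G * acc;
    }
    for (int i = 0; i < n; ++i) cpl[i] = cplLong[regionOf[i]];
    if (useLocal) cpl += L * svec;

    // noise increment (shared between predictor and corrector)
    if (noiseIncSd > 0.0) {
      for (int i = 0; i < n; ++i) xi[i] = noiseIncSd * R::norm_rand();
    } else xi.zeros();

    deriv(y, svec, cpl, t, k1);
    yp = y + dt * k1;
    yp.col(4) += xi;
    double t2 = t + dt;
    for (int i = 0; i < n; ++i)
      svecP[i] = sigm(yp(i, 1) - yp(i, 2) + stimAt(t2, i), e0, r, v0);
    // corrector reuses the coupling input of the step start (held over dt)
    deriv(yp, svecP, cpl, t2, k2);
    y += 0.5 * dt * (k1 + k2);
    y.col(4) += xi;

    if (!y.col(1).is_finite() || !y.col(2).is_finite())
      Rcpp::stop("non-finite state at step %d (t = %g s)", step, t);

    int done = step + 1;
    if (done > burnSteps && (done - burnSteps) % recordEvery == 0 && rec < nRec) {
      for (int i = 0; i < n; ++i) out(i, rec) = y(i, 1) - y(i, 2);
      tout[rec] = done * dt;
      ++rec;
    }
  }
  return Rcpp::List::create(Rcpp::Named("vpyr") = out.cols(0, rec - 1),
                            Rcpp::Named("time") = tout.subvec(0, rec - 1));
}
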