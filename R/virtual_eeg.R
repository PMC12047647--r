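# virtual_eeg: lead-field projection of simulated sources to electrode
# voltages plus spectral summaries (Welch PSD, spectrogram, band power).

#' Project simulated source activity to virtual EEG
#'
#' V(t) = LF . (sourceScale * v_pyr(t)), optionally re-referenced to the
#' common average (the default).
#'
#' @param sim a [SimOutput-class].
#' @param lf a [LeadFieldMatrix-class] whose columns match the simulation
#'   nodes (for region-mode simulations aggregate the mesh lead field
#'   first, see [aggregateLeadField()]).
#' @param sourceScale global dipole-moment scale (arbitrary units unless
#'   calibrated), default 1.
#' @param reference "average" or "electrode" (keep the solve reference).
#' @return an [EEGRecord-class]
#' @export
projectEEG <- function(sim, lf, sourceScale = 1,
                       reference = c("average", "electrode")) {
  reference <- match.arg(reference)
  m <- lf@lf
  if (ncol(m) != nrow(sim@vpyr))
    stop(sprintf("lead field has %d sources but simulation has %d nodes",
                 ncol(m), nrow(sim@vpyr)))
  v <- m %*% (sourceScale * sim@vpyr)
  if (reference == "average") v <- sweep(v, 2, colMeans(v))
  new("EEGRecord", labels = lf@electrodes, fs = sim@fs, data = v,
      reference = reference)
}

#' Aggregate a vertex lead field to region-level sources
#'
#' Region column = mean of the member-vertex columns; pairs a mesh-based
#' lead field with a region-mode simulation.
#'
#' @param lf a [LeadFieldMatrix-class] with one column per mesh vertex.
#' @param mesh the [CorticalMesh-class] the lead field was built on.
#' @return a [LeadFieldMatrix-class] with one column per region.
#' @export
aggregateLeadField <- function(lf, mesh) {
  reg <- mesh@region
  nR <- mesh@nRegions
  out <- matrix(0, nrow(lf@lf), nR)
  for (q in seq_len(nR)) {
    members <- which(reg == q)
    if (length(members))
      out[, q] <- rowMeans(lf@lf[, members, drop = FALSE])
  }
  rownames(out) <- lf@electrodes
  new("LeadFieldMatrix", lf = out, electrodes = lf@electrodes,
      reference = lf@reference, referenced = lf@referenced)
}

# Welch PSD of one signal: Hann window, mean removal per segment,
# density scaling (power/Hz); one-sided.
.welch1 <- function(x, fs, nperseg, noverlap) {
  n <- length(x)
  step <- nperseg - noverlap
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / nperseg)
  u <- sum(w^2)
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:nf])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  if (nperseg %% 2 == 1) psd[nf] <- 2 * psd[nf]
  psd
}

#' Welch power spectral density of an EEG record
#'
#' Averaged modified periodograms (Hann window, per-segment mean
#' removal, density scaling). Returns per-channel PSDs and the
#' channel-averaged PSD.
#'
#' @param rec an [EEGRecord-class] (or a plain matrix with `fs` given).
#' @param windowSec segment length, s (default 2).
#' @param overlap overlap fraction (default 0.5).
#' @param fs sampling rate when `rec` is a matrix.
#' @return a [SpectralResult-class]
#' @export
psdWelch <- function(rec, windowSec = 2, overlap = 0.5, fs = NULL) {
  if (is(rec, "EEGRecord")) { x <- rec@data; fs <- rec@fs }
  else { x <- rec; if (is.null(fs)) stop("fs required for matrix input") }
  if (is.null(dim(x))) x <- matrix(x, 1)
  nperseg <- round(windowSec * fs)
  if (nperseg > ncol(x)) nperseg <- ncol(x)
  noverlap <- floor(nperseg * overlap)
  nf <- nperseg %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / nperseg
  psd <- t(apply(x, 1, .welch1, fs = fs, nperseg = nperseg,
                 noverlap = noverlap))
  if (is(rec, "EEGRecord")) rownames(psd) <- rec@labels
  new("SpectralResult", freq = freq, psd = psd, channelMean = colMeans(psd),
      spectrogram = NULL, bandPower = NULL,
      meta = list(windowSec = windowSec, overlap = overlap, fs = fs,
                  estimator = "welch-hann"))
}

#' Short-time spectrogram of one channel
#'
#' Sliding Welch blocks: at each step a `windowSec` block is reduced to a
#' one-segment Hann periodogram.
#'
#' @param rec an [EEGRecord-class].
#' @param channel channel label or index.
#' @param windowSec block length, s.
#' @param stepSec hop between blocks, s.
#' @return a [SpectralResult-class] with the `spectrogram` slot set
#'   (time = block centres).
#' @export
spectrogramEEG <- function(rec, channel = 1, windowSec = 2, stepSec = 0.5) {
  if (is.character(channel)) channel <- match(channel, rec@labels)
  x <- rec@data[channel, ]
  fs <- rec@fs
  nper <- round(windowSec * fs)
  step <- max(1, round(stepSec * fs))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper)
  u <- sum(w^2)
  nf <- nper %/% 2 + 1
  pow <- matrix(0, length(starts), nf)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:nf])^2 / (fs * u)
    sp[2:(nf - 1)] <- 2 * sp[2:(nf - 1)]
    pow[k, ] <- sp
  }
  freq <- (seq_len(nf) - 1) * fs / nper
  tt <- (starts - 1 + nper / 2) / fs
  new("SpectralResult", freq = freq, psd = NULL, channelMean = NULL,
      spectrogram = list(time = tt, freq = freq, power = pow),
      bandPower = NULL,
      meta = list(windowSec = windowSec, stepSec = stepSec,
                  channel = rec@labels[channel]))
}

#' Per-channel band power (topography data)
#'
#' Trapezoidal integral of the Welch PSD over a frequency band, per
#' channel; pair with the montage positions for topographic maps.
#'
#' @param rec an [EEGRecord-class].
#' @param band numeric(2) band edges, Hz (default the alpha band 8-12).
#' @param windowSec,overlap Welch settings.
#' @return named numeric vector of band power per channel.
#' @export
bandTopography <- function(rec, band = c(8, 12), windowSec = 2,
                           overlap = 0.5) {
  sp <- psdWelch(rec, windowSec = windowSec, overlap = overlap)
  bandPowerFromPsd(sp, band)
}

#' Band power from an existing spectral result
#' @param sp a [SpectralResult-class] with per-channel PSD.
#' @param band numeric(2) band edges, Hz.
#' @return named numeric vector, one value per channel.
#' @export
bandPowerFromPsd <- function(sp, band) {
  sel <- which(sp@freq >= band[1] & sp@freq <= band[2])
  if (length(sel) < 2) stop("band too narrow for the frequency resolution")
  f <- sp@freq[sel]
  apply(sp@psd[, sel, drop = FALSE], 1, function(p)
    sum(diff(f) * (head(p, -1) + p[-1]) / 2))
}

#' Frequency of the PSD maximum above a floor frequency
#' @param sp a [SpectralResult-class] with a channel-mean PSD.
#' @param above consider only frequencies strictly above this, Hz.
#' @return peak frequency, Hz.
#' @export
psdPeakFrequency <- function(sp, above = 1) {
  sel <- which(sp@freq > above)
  sp@freq[sel[which.max(sp@channelMean[sel])]]
}
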