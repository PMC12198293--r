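#' Discrete prolate spheroidal (Slepian) sequences
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw` via the symmetric tridiagonal eigenproblem. For long
#' windows (`n > 1024`) the tapers are computed at length 1024 and
#' interpolated, then re-normalized to unit energy — adequate for spectral
#' estimation since the tapers are smooth.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 2.5, giving `2*nw - 1 = 4`
#'   well-concentrated tapers).
#' @param k number of tapers (default 4).
#' @return n x k matrix; columns are unit-energy tapers.
#' @export
dpss_tapers <- function(n, nw = 2.5, k = 4) {
  stopifnot(n >= 2, k >= 1, nw > 0, k <= n)
  n_eff <- min(n, 1024L)
  w <- nw / n_eff
  i <- seq_len(n_eff) - 1
  d <- ((n_eff - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (i[-1] * (n_eff - i[-1])) / 2
  A <- diag(d)
  A[cbind(seq_len(n_eff - 1), seq_len(n_eff - 1) + 1)] <- e
  A[cbind(seq_len(n_eff - 1) + 1, seq_len(n_eff - 1))] <- e
  ev <- eigen(A, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n_eff < n) {
    x0 <- seq(0, 1, length.out = n_eff)
    x1 <- seq(0, 1, length.out = n)
    h <- apply(h, 2, function(col) stats::approx(x0, col, x1)$y)
  }
  # unit energy; polarity convention: nonnegative mean, else positive start
  for (j in seq_len(k)) {
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
    m <- mean(h[, j])
    s <- if (abs(m) > 1e-10) sign(m) else sign(sum(h[seq_len(n %/% 2), j]))
    if (s < 0) h[, j] <- -h[, j]
  }
  h
}

#' Decimate an epoch set
#'
#' Zero-phase low-pass (4th-order Butterworth at 80% of the new Nyquist)
#' followed by sample decimation; used to bring epochs to a rate where the
#' 2 s multitaper window is cheap.
#'
#' @param epochs an `"epoch_set"`.
#' @param factor integer decimation factor.
#' @return the decimated epoch set.
#' @export
decimate_epochs <- function(epochs, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(epochs)
  fs_new <- epochs$fs / factor
  bf <- signal::butter(4, 0.8 * (fs_new / 2) / (epochs$fs / 2), type = "low")
  d <- dim(epochs$data)
  keep <- seq(1, d[3], by = factor)
  out <- array(NA_real_, c(d[1], d[2], length(keep)))
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      y <- signal::filtfilt(bf, epochs$data[tr, ch, ])
      out[tr, ch, ] <- y[keep]
    }
  epochs$data <- out
  epochs$fs <- fs_new
  epochs$time <- epochs$time[keep]
  epochs
}

#' Multitaper time-frequency power
#'
#' Sliding-window multitaper spectrogram: within each window the signal is
#' multiplied by `n_tapers` Slepian tapers, Fourier transformed, and the
#' squared amplitudes averaged over tapers. Power is reported per trial,
#' channel, frequency bin, and window center.
#'
#' @param epochs an `"epoch_set"`.
#' @param fmin,fmax frequency band of interest in Hz (defaults 12, 30).
#' @param window_s taper window length in seconds (default 2).
#' @param n_tapers number of Slepian tapers (default 4).
#' @param step_s window step in seconds (default 0.05).
#' @param time_bandwidth time-bandwidth product (default 2.5).
#' @return list of class `"mt_power"`: `power` (trial x channel x freq x
#'   time array), `freqs`, `times` (window centers on the epoch time
#'   axis), `fs`, plus the estimator settings.
#' @export
multitaper_power <- function(epochs, fmin = 12, fmax = 30, window_s = 2,
                             n_tapers = 4, step_s = 0.05,
                             time_bandwidth = 2.5) {
  fs <- epochs$fs
  if (fmax >= fs / 2 || fmin < 0 || fmin >= fmax)
    stop("frequency band must satisfy 0 <= fmin < fmax < fs/2",
         call. = FALSE)
  wlen <- round(window_s * fs)
  if (wlen < 2) stop("window too short", call. = FALSE)
  d <- dim(epochs$data)
  if (d[3] < wlen) stop("epoch shorter than the taper window", call. = FALSE)
  tap <- dpss_tapers(wlen, nw = time_bandwidth, k = n_tapers)
  fgrid <- (seq_len(wlen) - 1) / wlen * fs
  fsel <- which(fgrid >= fmin & fgrid <= fmax + 1e-9)
  step_n <- max(1L, round(step_s * fs))
  starts <- seq(1L, d[3] - wlen + 1L, by = step_n)
  centers <- epochs$time[starts] + (wlen - 1) / (2 * fs)
  power <- array(NA_real_, c(d[1], d[2], length(fsel), length(starts)))
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      seg <- vapply(starts, function(s) x[s:(s + wlen - 1L)],
                    numeric(wlen))          # wlen x n_windows
      for (j in seq_len(n_tapers)) {
        sp <- stats::mvfft(seg * tap[, j])
        p <- Mod(sp[fsel, , drop = FALSE])^2
        power[tr, ch, , ] <- if (j == 1) p / n_tapers else
          power[tr, ch, , ] + p / n_tapers
      }
    }
  structure(list(power = power, freqs = fgrid[fsel], times = centers,
                 fs = fs, window_s = window_s, n_tapers = n_tapers,
                 time_bandwidth = time_bandwidth),
            class = "mt_power")
}

#' Percent-change baselining of multitaper power
#'
#' For each trial, channel, and frequency, expresses power as
#' `100 * (P - mean(P_baseline)) / mean(P_baseline)` with the baseline mean
#' taken over the baseline window of that same trial, then averages across
#' trials. Normalization is per trial, before averaging.
#'
#' @param mt an `"mt_power"`.
#' @param baseline_window length-2 numeric in epoch-time seconds. The
#'   default (-1.56, -0.56) is the -1..0 s window before audio onset when
#'   epochs are aligned to the target word (audio leads it by 0.56 s).
#' @return list of class `"tfr_map"`: `pct` (channel x freq x time,
#'   trial-averaged), `pct_trials` (trial x channel x freq x time),
#'   `freqs`, `times`, `baseline_window`.
#' @export
percent_change <- function(mt, baseline_window = c(-1.56, -0.56)) {
  bsel <- which(mt$times >= baseline_window[1] &
                  mt$times <= baseline_window[2])
  if (!length(bsel))
    stop("baseline window contains no time bins", call. = FALSE)
  d <- dim(mt$power)
  pct <- array(NA_real_, d)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      p <- mt$power[tr, ch, , , drop = TRUE]
      p <- matrix(p, d[3], d[4])
      b <- rowMeans(p[, bsel, drop = FALSE])
      if (any(b <= .Machine$double.eps))
        stop("baseline power is zero; cannot compute percent change",
             call. = FALSE)
      pct[tr, ch, , ] <- 100 * (p - b) / b
    }
  avg <- apply(pct, c(2, 3, 4), mean)
  structure(list(pct = avg, pct_trials = pct, freqs = mt$freqs,
                 times = mt$times, baseline_window = baseline_window),
            class = "tfr_map")
}

#' Baseline t-test mask for time-frequency maps
#'
#' Pixelwise paired t-test of per-trial power against that trial's
#' baseline mean (equivalently, a one-sample t-test of the per-trial
#' percent change against zero), uncorrected. The mask is intended for
#' visualization only; inferential statistics in this pipeline are
#' resampling-based.
#'
#' @param tfr a `"tfr_map"` (needs `pct_trials`).
#' @param alpha significance level (default 0.05).
#' @return logical channel x freq x time array, with attribute
#'   `visualization_only = TRUE`.
#' @export
baseline_ttest_mask <- function(tfr, alpha = 0.05) {
  d <- dim(tfr$pct_trials)
  if (d[1] < 2)
    stop("baseline t-test needs at least 2 trials", call. = FALSE)
  n <- d[1]
  m <- apply(tfr$pct_trials, c(2, 3, 4), mean)
  s <- apply(tfr$pct_trials, c(2, 3, 4), stats::sd)
  tstat <- m / (s / sqrt(n))
  tstat[s == 0] <- 0
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  mask <- p < alpha
  attr(mask, "visualization_only") <- TRUE
  mask
}

# analytic signal via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Beta-band Hilbert envelope
#'
#' Zero-phase 4th-order Butterworth band-pass (12-30 Hz by default)
#' followed by the magnitude of the analytic signal, with optional
#' anti-aliased downsampling to `fs_env` for TRF fitting.
#'
#' @param epochs an `"epoch_set"`.
#' @param band band edges in Hz (default `c(12, 30)`).
#' @param fs_env output sampling rate in Hz (default 100); `NULL` keeps
#'   the input rate. Must divide `fs`.
#' @param order Butterworth order (default 4).
#' @return list of class `"envelope_set"`: `envelope` (trial x channel x
#'   sample, nonnegative), `fs_env`, `time`, `band`, `channels`, `meta`.
#' @export
beta_envelope <- function(epochs, band = c(12, 30), fs_env = 100,
                          order = 4) {
  fs <- epochs$fs
  if (band[1] >= band[2])
    stop("band must satisfy fmin < fmax", call. = FALSE)
  if (band[2] >= fs / 2)
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  d <- dim(epochs$data)
  env <- array(NA_real_, d)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      y <- signal::filtfilt(bf, epochs$data[tr, ch, ])
      env[tr, ch, ] <- Mod(analytic_signal(y))
    }
  time <- epochs$time
  if (!is.null(fs_env) && fs_env < fs) {
    factor <- fs / fs_env
    if (abs(factor - round(factor)) > 1e-9)
      stop("fs_env must divide fs", call. = FALSE)
    factor <- as.integer(round(factor))
    lp <- signal::butter(4, 0.8 * (fs_env / 2) / (fs / 2), type = "low")
    keep <- seq(1, d[3], by = factor)
    out <- array(NA_real_, c(d[1], d[2], length(keep)))
    for (tr in seq_len(d[1]))
      for (ch in seq_len(d[2])) {
        y <- signal::filtfilt(lp, env[tr, ch, ])
        out[tr, ch, ] <- y[keep]
      }
    env <- pmax(out, 0)
    time <- time[keep]
  } else {
    fs_env <- fs
  }
  structure(list(envelope = env, fs_env = fs_env, time = time,
                 band = band, channels = epochs$channels,
                 meta = epochs$meta),
            class = "envelope_set")
}
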