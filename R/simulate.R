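#' Simulation configuration for a synthetic two-speaker LFP session
#'
#' Bundles and validates the parameters of the synthetic-session generator.
#' Defaults reproduce the study conditions the analysis assumes: 96 trials
#' of ~3.18 s two-stream sentences sampled at 2 kHz on two quadripolar DBS
#' electrodes (4 monopolar contacts per hemisphere), word-onset intervals
#' with mean 353 ms / SD 134 ms in the attended stream and 411 ms / 137 ms
#' in the unattended stream, and a behavioral accuracy of 81%.
#'
#' The forward model is multiplicative: the beta-band envelope of the clean
#' signal component equals a resting level plus the half-wave-rectified sum
#' over streams of (onset impulse train convolved with that stream's
#' kernel), and this modulator scales a narrowband carrier at the center of
#' the 12-30 Hz band. Broadband Gaussian noise is added per contact.
#'
#' @param n_trials number of trials (default 96).
#' @param fs sampling rate in Hz (default 2000); must exceed twice the upper
#'   carrier band edge.
#' @param sentence_duration_s duration of the sentence (word-onset window)
#'   in seconds, measured from the target-word onset (default 3.18).
#' @param baseline_duration_s silent pre-speech baseline per trial in
#'   seconds (default 1).
#' @param speech_lead_s interval between audio onset and the target-word
#'   onset in seconds (default 0.56).
#' @param interval_mean_ms,interval_sd_ms length-2 numeric vectors giving
#'   the word-onset interval mean and SD in milliseconds for the
#'   (attended, unattended) streams. Defaults c(353, 411) and c(134, 137).
#' @param carrier_band beta band edges in Hz (default c(12, 30)); the
#'   carrier frequency is the band center.
#' @param kernels list of two kernel descriptions (attended, unattended) as
#'   returned by [gaussian_kernel()]; each spans at most 0.7 s of lag.
#' @param resting_level baseline envelope level in signal units
#'   (default 0.2), so that pre-speech beta power is nonzero.
#' @param noise_sd SD of the additive white noise per monopolar contact
#'   (default 0.5).
#' @param snr_scale unitless multiplier applied to both kernels
#'   (default 1); 0 yields a no-signal session.
#' @param contact_gains per-contact gain of the clean component (length
#'   `n_contacts_per_hemisphere`); adjacent gains must differ so bipolar
#'   derivations retain signal.
#' @param n_contacts_per_hemisphere,n_hemispheres electrode geometry
#'   (defaults 4 and 2).
#' @param behavioral_accuracy probability a trial is answered correctly
#'   (default 0.81).
#' @param gap_s inter-trial gap in seconds (default 0.75).
#' @param seed integer seed for the session (default 1).
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_trials = 96,
                       fs = 2000,
                       sentence_duration_s = 3.18,
                       baseline_duration_s = 1,
                       speech_lead_s = 0.56,
                       interval_mean_ms = c(attended = 353, unattended = 411),
                       interval_sd_ms = c(attended = 134, unattended = 137),
                       carrier_band = c(12, 30),
                       kernels = default_kernels(),
                       resting_level = 0.2,
                       noise_sd = 0.5,
                       snr_scale = 1,
                       contact_gains = c(1, 0.75, 0.55, 0.4),
                       n_contacts_per_hemisphere = 4,
                       n_hemispheres = 2,
                       behavioral_accuracy = 0.81,
                       gap_s = 0.75,
                       seed = 1L) {
  stopifnot(n_trials >= 1, sentence_duration_s > 0, baseline_duration_s >= 0)
  if (any(interval_mean_ms <= 0))
    stop("interval_mean_ms must be positive", call. = FALSE)
  if (any(interval_sd_ms < 0))
    stop("interval_sd_ms must be nonnegative", call. = FALSE)
  if (fs <= 2 * carrier_band[2])
    stop("fs must exceed twice the upper carrier band edge", call. = FALSE)
  if (behavioral_accuracy < 0 || behavioral_accuracy > 1)
    stop("behavioral_accuracy must lie in [0, 1]", call. = FALSE)
  for (k in kernels) {
    if (k$span_s > 0.7 + 1e-12)
      stop("kernel span must not exceed 0.7 s", call. = FALSE)
  }
  if (length(contact_gains) != n_contacts_per_hemisphere)
    stop("contact_gains must have one entry per contact", call. = FALSE)
  cfg <- list(
    n_trials = as.integer(n_trials), fs = fs,
    sentence_duration_s = sentence_duration_s,
    baseline_duration_s = baseline_duration_s,
    speech_lead_s = speech_lead_s,
    interval_mean_ms = interval_mean_ms, interval_sd_ms = interval_sd_ms,
    carrier_band = carrier_band, kernels = kernels,
    resting_level = resting_level, noise_sd = noise_sd,
    snr_scale = snr_scale, contact_gains = contact_gains,
    n_contacts_per_hemisphere = as.integer(n_contacts_per_hemisphere),
    n_hemispheres = as.integer(n_hemispheres),
    behavioral_accuracy = behavioral_accuracy,
    gap_s = gap_s, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Gaussian lag-domain TRF kernel description
#'
#' A smooth nonnegative bump over the 0-0.7 s lag window, used as the
#' ground-truth onset response of one speech stream.
#'
#' @param amp peak amplitude in signal units.
#' @param peak_s lag of the peak in seconds.
#' @param sd_s Gaussian width in seconds.
#' @param span_s total lag span in seconds (default 0.7).
#' @return list of class `"trf_kernel"`.
#' @export
gaussian_kernel <- function(amp = 1, peak_s = 0.15, sd_s = 0.05,
                            span_s = 0.7) {
  stopifnot(span_s > 0, sd_s > 0)
  structure(list(amp = amp, peak_s = peak_s, sd_s = sd_s, span_s = span_s),
            class = "trf_kernel")
}

#' Default ground-truth kernels for the two streams
#'
#' The attended stream drives a stronger, earlier response than the
#' unattended stream; both are nonnegative so the rectification in the
#' forward model is inactive and the generative model stays linear.
#' @return named list with elements `attended` and `unattended`.
#' @export
default_kernels <- function() {
  list(attended   = gaussian_kernel(amp = 1.0, peak_s = 0.15, sd_s = 0.05),
       unattended = gaussian_kernel(amp = 0.6, peak_s = 0.20, sd_s = 0.06))
}

#' Evaluate a kernel on a lag grid
#'
#' @param kernel a `"trf_kernel"` or a plain numeric vector (returned
#'   unchanged).
#' @param fs sampling rate of the lag grid in Hz.
#' @return numeric vector of weights at lags `0, 1/fs, ..., span_s`.
#' @export
kernel_weights <- function(kernel, fs) {
  if (is.numeric(kernel)) return(kernel)
  stopifnot(inherits(kernel, "trf_kernel"))
  lags <- seq(0, kernel$span_s, by = 1 / fs)
  kernel$amp * exp(-(lags - kernel$peak_s)^2 / (2 * kernel$sd_s^2))
}

#' Sample one word-onset train
#'
#' Draws irregular onset times whose successive differences follow a gamma
#' distribution moment-matched to the requested mean and SD (positive
#' support, two free moments), truncated below at 50 ms by rejection to
#' avoid unphysically short words. The first onset is at time 0 and the
#' train fills `[0, duration_s)`. With `interval_sd_ms = 0` the intervals
#' are exactly `interval_mean_ms`.
#'
#' @param interval_mean_ms,interval_sd_ms interval moments in milliseconds.
#' @param duration_s train duration in seconds.
#' @param min_interval_ms lower truncation bound (default 50).
#' @return numeric vector of onset times in seconds, strictly increasing,
#'   starting at 0.
#' @export
sample_onset_train <- function(interval_mean_ms, interval_sd_ms, duration_s,
                               min_interval_ms = 50) {
  if (interval_mean_ms <= 0)
    stop("interval_mean_ms must be positive", call. = FALSE)
  if (interval_sd_ms < 0)
    stop("interval_sd_ms must be nonnegative", call. = FALSE)
  if (duration_s <= 0)
    stop("duration_s must be positive", call. = FALSE)
  draw <- function(n) {
    if (interval_sd_ms == 0) return(rep(interval_mean_ms, n))
    shape <- (interval_mean_ms / interval_sd_ms)^2
    rate <- shape / interval_mean_ms
    x <- stats::rgamma(n, shape = shape, rate = rate)
    while (any(bad <- x < min_interval_ms))
      x[bad] <- stats::rgamma(sum(bad), shape = shape, rate = rate)
    x
  }
  onsets <- 0
  # expected count plus slack; top up in the rare case the draw runs short
  n_guess <- max(8L, ceiling(1.5 * duration_s * 1000 / interval_mean_ms) + 4L)
  repeat {
    iv <- draw(n_guess)
    cand <- cumsum(c(onsets[length(onsets)], iv / 1000))
    onsets <- c(onsets, cand[-1])
    if (onsets[length(onsets)] >= duration_s) break
  }
  onsets[onsets < duration_s]
}

#' Synthesize one trial of multichannel LFP
#'
#' Builds the clean modulator (resting level plus rectified sum of
#' onset-train/kernel convolutions), multiplies it onto a narrowband
#' carrier with a random per-trial phase, scales it by per-contact gains,
#' and adds white noise.
#'
#' @param onset_trains named list (`attended`, `unattended`) of onset times
#'   in seconds relative to the target-word onset.
#' @param kernels named list of kernels matching `onset_trains`.
#' @param config a [sim_config()].
#' @return list with `signal` (samples x contacts matrix), `modulator`
#'   (the clean envelope), and `t` (time in seconds relative to the
#'   target-word onset).
#' @export
synthesize_trial <- function(onset_trains, kernels, config) {
  fs <- config$fs
  pre <- config$baseline_duration_s + config$speech_lead_s
  post <- config$sentence_duration_s + 0.7
  n <- round((pre + post) * fs)
  t <- (seq_len(n) - 1) / fs - pre
  trial_len <- pre + post
  modulator <- rep(config$resting_level, n)
  for (s in names(onset_trains)) {
    kw <- config$snr_scale * kernel_weights(kernels[[s]], fs)
    if (length(kw) / fs > trial_len)
      stop("kernel longer than trial", call. = FALSE)
    for (o in onset_trains[[s]]) {
      i0 <- round((o + pre) * fs) + 1
      idx <- i0:min(n, i0 + length(kw) - 1)
      modulator[idx] <- modulator[idx] + kw[seq_along(idx)]
    }
  }
  modulator <- pmax(modulator, 0)
  f0 <- mean(config$carrier_band)
  phase <- stats::runif(1, 0, 2 * pi)
  clean <- modulator * sin(2 * pi * f0 * t + phase)
  n_ch <- config$n_hemispheres * config$n_contacts_per_hemisphere
  gains <- rep(config$contact_gains, times = config$n_hemispheres)
  sig <- outer(clean, gains)
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(n * n_ch, sd = config$noise_sd), n, n_ch)
  list(signal = sig, modulator = modulator, t = t)
}

#' Simulate a full recording session
#'
#' Generates `n_trials` trials laid out in one continuous multichannel
#' recording with inter-trial gaps, plus the event table and the ground
#' truth (kernels, per-trial onset trains, correctness flags). The result
#' is bit-identical for a fixed config (the config's `seed` is applied at
#' entry).
#'
#' @param config a [sim_config()].
#' @return list of class `"lfp_session"` with elements
#'   \describe{
#'     \item{recording}{list: `data` (samples x channels matrix), `fs`,
#'       `channels` (labels `L0..L3`, `R0..R3`)}
#'     \item{events}{data.frame: `trial_id`, `stream`, `onset_time_s`
#'       (absolute), `is_target_word`, `trial_correct`}
#'     \item{truth}{list: `kernels`, `onsets` (per trial, per stream,
#'       relative to target-word onset), `correct`, `target_time_s`}
#'     \item{config}{the config used}
#'   }
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  pre <- config$baseline_duration_s + config$speech_lead_s
  post <- config$sentence_duration_s + 0.7
  trial_n <- round((pre + post) * fs)
  gap_n <- round(config$gap_s * fs)
  n_ch <- config$n_hemispheres * config$n_contacts_per_hemisphere
  total_n <- config$n_trials * (trial_n + gap_n) + gap_n
  data <- matrix(0, total_n, n_ch)
  if (config$noise_sd > 0)
    data[] <- stats::rnorm(length(data), sd = config$noise_sd)

  correct <- stats::runif(config$n_trials) < config$behavioral_accuracy
  streams <- c("attended", "unattended")
  onsets <- vector("list", config$n_trials)
  target_time <- numeric(config$n_trials)
  ev <- list()
  for (k in seq_len(config$n_trials)) {
    tr <- lapply(streams, function(s) {
      sample_onset_train(config$interval_mean_ms[[s]],
                         config$interval_sd_ms[[s]],
                         config$sentence_duration_s)
    })
    names(tr) <- streams
    onsets[[k]] <- tr
    syn <- synthesize_trial(tr, config$kernels, config)
    i0 <- gap_n + (k - 1) * (trial_n + gap_n)
    # trial noise was pre-drawn for the whole record; replace the segment
    data[i0 + seq_len(trial_n), ] <- syn$signal
    target_time[k] <- (i0 + round(pre * fs)) / fs
    for (s in streams) {
      ev[[length(ev) + 1]] <- data.frame(
        trial_id = k, stream = s,
        onset_time_s = target_time[k] + tr[[s]],
        is_target_word = s == "attended" &
          seq_along(tr[[s]]) == 1L,
        trial_correct = correct[k]
      )
    }
  }
  channels <- as.vector(t(outer(c("L", "R")[seq_len(config$n_hemispheres)],
                                seq_len(config$n_contacts_per_hemisphere) - 1,
                                paste0)))
  session <- list(
    recording = list(data = data, fs = fs, channels = channels),
    events = do.call(rbind, ev),
    truth = list(kernels = config$kernels, onsets = onsets,
                 correct = correct, target_time_s = target_time),
    config = config
  )
  class(session) <- "lfp_session"
  session
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf(
    "<lfp_session> %d trials, %d channels @ %g Hz, %.1f s total\n",
    x$config$n_trials, ncol(x$recording$data), x$recording$fs,
    nrow(x$recording$data) / x$recording$fs))
  invisible(x)
}

#' Interval statistics of a session's generated onset trains
#'
#' Pools inter-onset intervals across trials per stream and reports their
#' mean and SD in milliseconds, mirroring how stimulus interval statistics
#' are summarized.
#'
#' @param session an `"lfp_session"`.
#' @return data.frame with columns `stream`, `n_intervals`, `mean_ms`,
#'   `sd_ms`.
#' @export
interval_stats <- function(session) {
  streams <- c("attended", "unattended")
  do.call(rbind, lapply(streams, function(s) {
    iv <- unlist(lapply(session$truth$onsets,
                        function(tr) diff(tr[[s]]))) * 1000
    data.frame(stream = s, n_intervals = length(iv),
               mean_ms = mean(iv), sd_ms = stats::sd(iv))
  }))
}
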