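#' Default bipolar montage for quadripolar DBS electrodes
#'
#' Adjacent-contact derivations 0-1, 1-2, 2-3 per hemisphere, so a
#' 4-contact electrode yields 3 bipolar channels per side.
#'
#' @param n_contacts contacts per hemisphere (default 4).
#' @param hemispheres hemisphere prefixes (default `c("L", "R")`).
#' @return data.frame with columns `anode`, `cathode`, `label`,
#'   `hemisphere`, `montage`.
#' @export
default_montage <- function(n_contacts = 4, hemispheres = c("L", "R")) {
  do.call(rbind, lapply(hemispheres, function(h) {
    i <- seq_len(n_contacts - 1) - 1
    data.frame(anode = paste0(h, i), cathode = paste0(h, i + 1),
               label = paste0(h, i, "-", h, i + 1),
               hemisphere = h, montage = paste0(i, "-", i + 1))
  }))
}

#' Bipolar re-referencing
#'
#' Subtracts each montage pair's cathode from its anode, suppressing
#' far-field common-mode signal and increasing spatial selectivity.
#'
#' @param recording list with `data` (samples x channels), `fs`,
#'   `channels`.
#' @param montage data.frame as from [default_montage()].
#' @return a recording with one channel per montage pair, labelled
#'   `"anode-cathode"`.
#' @export
make_bipolar <- function(recording, montage = default_montage()) {
  missing <- setdiff(c(montage$anode, montage$cathode), recording$channels)
  if (length(missing))
    stop("channel(s) not found in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ia <- match(montage$anode, recording$channels)
  ic <- match(montage$cathode, recording$channels)
  out <- recording
  out$data <- recording$data[, ia, drop = FALSE] -
    recording$data[, ic, drop = FALSE]
  out$channels <- montage$label
  out$montage <- montage
  out
}

#' Epoch a continuous recording around target-word onsets
#'
#' Cuts one epoch per trial, aligned so that t = 0 is the target-word
#' onset. The default window (-1.56, 3.18) s contains the -1..0 s
#' pre-audio baseline (the audio starts ~0.56 s before the target word)
#' and the full sentence.
#'
#' @param recording a (typically bipolar) recording.
#' @param events event table as produced by [simulate_session()]; rows with
#'   `is_target_word` define per-trial time origins, `trial_correct` the
#'   correctness metadata.
#' @param window length-2 numeric, epoch window in seconds relative to the
#'   target-word onset.
#' @return list of class `"epoch_set"` with `data` (trial x channel x
#'   sample array), `fs`, `time`, `channels`, and a `meta` data.frame
#'   (`trial_id`, `correct`, `rejected`, `reason`, `retained`).
#' @export
epoch_recording <- function(recording, events, window = c(-1.56, 3.18)) {
  stopifnot(window[2] > window[1])
  tw <- events[events$is_target_word, , drop = FALSE]
  tw <- tw[order(tw$trial_id), , drop = FALSE]
  if (!nrow(tw)) stop("no target-word events found", call. = FALSE)
  fs <- recording$fs
  n_rec <- nrow(recording$data)
  i_rel <- round(window[1] * fs):round(window[2] * fs)
  n_s <- length(i_rel)
  n_tr <- nrow(tw)
  n_ch <- ncol(recording$data)
  data <- array(NA_real_, c(n_tr, n_ch, n_s))
  for (k in seq_len(n_tr)) {
    i0 <- round(tw$onset_time_s[k] * fs)
    idx <- i0 + i_rel + 1L
    if (idx[1] < 1 || idx[n_s] > n_rec)
      stop(sprintf("epoch window for trial %d exceeds recording bounds",
                   tw$trial_id[k]), call. = FALSE)
    data[k, , ] <- t(recording$data[idx, , drop = FALSE])
  }
  structure(list(
    data = data, fs = fs, time = i_rel / fs, channels = recording$channels,
    t0_definition = "target-word onset", window = window,
    meta = data.frame(trial_id = tw$trial_id, correct = tw$trial_correct,
                      rejected = FALSE, reason = NA_character_,
                      retained = TRUE)
  ), class = "epoch_set")
}

#' Flag artifact trials by a pooled z-score criterion
#'
#' Standardizes each channel with the mean and SD pooled over all trials
#' and samples of that channel, and flags any trial containing a sample
#' with |z| at or above the threshold. Flags are monotone: trials already
#' rejected stay rejected. Trials are flagged, never deleted.
#'
#' @param epochs an `"epoch_set"`.
#' @param z_threshold rejection threshold in pooled SDs (default 6).
#' @return the epoch set with updated `meta$rejected`/`reason`/`retained`.
#' @export
reject_artifact_trials <- function(epochs, z_threshold = 6) {
  if (dim(epochs$data)[1] < 2)
    stop("artifact rejection needs at least 2 trials", call. = FALSE)
  n_ch <- dim(epochs$data)[2]
  flagged <- rep(FALSE, dim(epochs$data)[1])
  for (ch in seq_len(n_ch)) {
    x <- epochs$data[, ch, ]
    mu <- mean(x)
    sdv <- stats::sd(as.vector(x))
    if (sdv == 0) next
    z <- abs(x - mu) / sdv
    flagged <- flagged | apply(z, 1, max) >= z_threshold
  }
  newly <- flagged & !epochs$meta$rejected
  epochs$meta$rejected <- epochs$meta$rejected | flagged
  epochs$meta$reason[newly] <- sprintf("z>=%g", z_threshold)
  epochs$meta$retained <- epochs$meta$retained & !epochs$meta$rejected
  epochs$n_rejected_artifact <- sum(flagged)
  epochs
}

#' Retain only correctly answered trials
#'
#' Marks trials answered incorrectly as not retained (rejection flags from
#' artifact screening are preserved; retention requires both criteria).
#'
#' @param epochs an `"epoch_set"` with correctness metadata.
#' @return the epoch set with updated `meta$retained`.
#' @export
keep_correct_trials <- function(epochs) {
  if (is.null(epochs$meta$correct) || anyNA(epochs$meta$correct))
    stop("correctness metadata missing", call. = FALSE)
  epochs$meta$retained <- !epochs$meta$rejected & epochs$meta$correct
  epochs$n_retained <- sum(epochs$meta$retained)
  epochs
}

#' Subset an epoch set to its retained trials
#'
#' @param epochs an `"epoch_set"`.
#' @return the epoch set containing only trials with `meta$retained`.
#' @export
retained_epochs <- function(epochs) {
  keep <- which(epochs$meta$retained)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$meta <- epochs$meta[keep, , drop = FALSE]
  epochs
}

#' Per-trial QC report
#'
#' @param epochs an `"epoch_set"`.
#' @return data.frame: `trial_id`, `rejected`, `reason`, `correct`,
#'   `retained`.
#' @export
qc_report <- function(epochs) {
  epochs$meta[, c("trial_id", "rejected", "reason", "correct", "retained")]
}

#' Behavioral percent correct
#'
#' @param trial_flags logical vector of per-trial correctness.
#' @return percentage of correct trials.
#' @export
percent_correct <- function(trial_flags) {
  if (!length(trial_flags)) stop("no trials", call. = FALSE)
  100 * mean(trial_flags)
}

#' Chance level of the color-number response task
#'
#' One of `n_colors` colors and one of `n_numbers` numbers must both be
#' reported; random guessing succeeds with probability
#' `1 / (n_colors * n_numbers)`.
#'
#' @param n_colors,n_numbers response-set sizes (defaults 4 and 4).
#' @return chance level as a percentage (6.25 for the 4 x 4 task).
#' @export
chance_level <- function(n_colors = 4, n_numbers = 4) {
  stopifnot(n_colors >= 1, n_numbers >= 1)
  100 / (n_colors * n_numbers)
}
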