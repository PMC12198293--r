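# Small simulated sessions and prepared TRF inputs shared across tests.

make_test_session <- function(n_trials = 15, fs = 200, noise_sd = 0,
                              snr_scale = 1, seed = 42,
                              kernels = default_kernels(),
                              behavioral_accuracy = 1, ...) {
  cfg <- sim_config(n_trials = n_trials, fs = fs, noise_sd = noise_sd,
                    snr_scale = snr_scale, seed = seed, kernels = kernels,
                    behavioral_accuracy = behavioral_accuracy, ...)
  simulate_session(cfg)
}

# run preprocessing + envelope extraction; return pieces for TRF fitting
prep_trf_inputs <- function(session, fs_env = 50, channel = 1,
                            fit_window = c(0, 2.93)) {
  bip <- make_bipolar(session$recording, default_montage(
    n_contacts = session$config$n_contacts_per_hemisphere,
    hemispheres = c("L", "R")[seq_len(session$config$n_hemispheres)]))
  ep <- epoch_recording(bip, session$events)
  ep <- reject_artifact_trials(ep)
  ep <- keep_correct_trials(ep)
  kept <- which(ep$meta$retained)
  env <- beta_envelope(retained_epochs(ep), fs_env = fs_env)
  trains <- session$truth$onsets[ep$meta$trial_id[kept]]
  list(
    epochs = ep, env = env, onset_trains = trains,
    stim = onset_stimulus(trains, fit_window = fit_window, fs_env = fs_env),
    env_list = envelope_responses(env, channel, fit_window = fit_window),
    fs_env = fs_env, fit_window = fit_window
  )
}

# minimal epoch_set for tests that construct signals directly
make_epochs <- function(data, fs, t_start = 0) {
  d <- dim(data)
  structure(list(
    data = data, fs = fs, time = t_start + (seq_len(d[3]) - 1) / fs,
    channels = paste0("ch", seq_len(d[2])),
    meta = data.frame(trial_id = seq_len(d[1]), correct = TRUE,
                      rejected = FALSE, reason = NA_character_,
                      retained = TRUE)
  ), class = "epoch_set")
}

# independent ridge oracle: least squares on the centered design augmented
# with sqrt(lambda) * I rows
ridge_oracle <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  Xa <- rbind(Xc, sqrt(lambda) * diag(ncol(X)))
  ya <- c(yc, rep(0, ncol(X)))
  w <- qr.coef(qr(Xa), ya)
  list(weights = unname(w), intercept = ym - sum(xm * w))
}
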