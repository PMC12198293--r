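#' Interval-preserving onset shuffle
#'
#' Randomizes a word-onset train while exactly preserving the multiset of
#' inter-onset intervals: the intervals are randomly permuted and the
#' initial offset is redrawn uniformly so the whole train still fits in
#' the trial. This destroys the alignment between onsets and the neural
#' signal but keeps the train's temporal statistics.
#'
#' @param onsets numeric vector of onset times in seconds, increasing.
#' @param duration_s trial duration in seconds; all shuffled onsets lie in
#'   `[0, duration_s)`.
#' @return shuffled onset-time vector, same length, increasing.
#' @export
shuffle_onsets <- function(onsets, duration_s) {
  stopifnot(length(onsets) >= 1, duration_s > 0)
  if (length(onsets) == 1) {
    message("single onset: only the offset is redrawn")
    return(stats::runif(1, 0, duration_s))
  }
  iv <- diff(onsets)
  perm <- if (length(iv) > 1) sample(iv) else iv
  span <- sum(iv)
  if (span >= duration_s)
    stop("onset train does not fit in the trial", call. = FALSE)
  offset <- stats::runif(1, 0, duration_s - span)
  offset + cumsum(c(0, perm))
}

#' Bootstrap distribution of real tracking performance
#'
#' Resamples (stimulus, response) trial pairs with replacement, keeping
#' each trial's pairing and within-trial onset structure intact, and
#' recomputes the cross-validated mean prediction correlation per
#' replicate.
#'
#' @param stim_list,env_list per-trial stimulus matrices and response
#'   vectors (paired).
#' @param n_boot number of bootstrap replicates (default 100).
#' @param n_folds,ridge_lambda,lag_min,lag_max,fs_env passed to
#'   [crossval_corr()].
#' @param seed RNG seed; `NULL` uses the current state.
#' @return numeric vector of `n_boot` mean correlations.
#' @export
bootstrap_real <- function(stim_list, env_list, n_boot = 100, n_folds = 5,
                           ridge_lambda = 1, lag_min = 0, lag_max = 0.7,
                           fs_env, seed = NULL) {
  if (n_boot < 2)
    stop("n_boot must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(stim_list)
  vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    crossval_corr(stim_list[idx], env_list[idx], n_folds = n_folds,
                  ridge_lambda = ridge_lambda, lag_min = lag_min,
                  lag_max = lag_max, fs_env = fs_env)$mean_r
  }, numeric(1))
}

#' Shuffle-null distribution of tracking performance
#'
#' Each replicate applies the interval-preserving shuffle independently to
#' every trial and stream (the neural data are untouched), rebuilds the
#' binary stimulus vectors, and recomputes the cross-validated mean
#' correlation.
#'
#' @param onset_trains per-trial named lists of onset-time vectors.
#' @param env_list per-trial response vectors.
#' @param n_null number of null replicates (default 500).
#' @param streams stimulus features to include.
#' @param duration_s trial (sentence) duration used by the shuffle.
#' @param fit_window,fs_env stimulus-vector construction parameters.
#' @param n_folds,ridge_lambda,lag_min,lag_max passed to
#'   [crossval_corr()].
#' @param seed RNG seed; `NULL` uses the current state.
#' @return numeric vector of `n_null` mean correlations.
#' @export
null_distribution <- function(onset_trains, env_list, n_null = 500,
                              streams = c("attended", "unattended"),
                              duration_s = 3.18, fit_window = c(0, 2.93),
                              fs_env, n_folds = 5, ridge_lambda = 1,
                              lag_min = 0, lag_max = 0.7, seed = NULL) {
  if (n_null < 20)
    warning("n_null < 20: empirical p resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_null), function(r) {
    shuffled <- lapply(onset_trains, function(tr) {
      out <- lapply(streams, function(s) shuffle_onsets(tr[[s]], duration_s))
      names(out) <- streams
      out
    })
    stim <- onset_stimulus(shuffled, streams = streams,
                           fit_window = fit_window, fs_env = fs_env)
    crossval_corr(stim, env_list, n_folds = n_folds,
                  ridge_lambda = ridge_lambda, lag_min = lag_min,
                  lag_max = lag_max, fs_env = fs_env)$mean_r
  }, numeric(1))
}

#' One-sided empirical p-value with add-one correction
#'
#' `p = (1 + #(null >= observed)) / (1 + n_null)`, so p is never zero.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of null statistics.
#' @return empirical p in `(0, 1]`.
#' @export
empirical_p <- function(observed, null_values) {
  if (!length(null_values))
    stop("null distribution is empty", call. = FALSE)
  if (!is.finite(observed) || any(!is.finite(null_values)))
    stop("non-finite inputs", call. = FALSE)
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Per-contact significance of word-onset tracking
#'
#' Runs the full inferential pipeline for one contact: observed 5-fold CV
#' mean correlation, optional bootstrap distribution of the real data,
#' interval-preserving shuffle null, and the empirical p of the observed
#' correlation against the null.
#'
#' @param onset_trains per-trial named lists of onset times (seconds
#'   relative to the target word).
#' @param env_list per-trial envelope responses for this contact.
#' @param streams stimulus features; a single stream gives the per-stream
#'   variant.
#' @param n_boot bootstrap replicates (default 100); 0 skips the
#'   bootstrap.
#' @param n_null shuffle-null replicates (default 500).
#' @param alpha significance level (default 0.05).
#' @param duration_s,fit_window,fs_env,n_folds,ridge_lambda,lag_min,lag_max
#'   pipeline parameters, as elsewhere.
#' @param seed RNG seed for fold assignment, bootstrap, and null.
#' @return list of class `"contact_result"`: `mean_r_observed`,
#'   `boot_r` (or NULL), `mean_r_boot`, `null_r`, `p`, `significant`,
#'   `alpha`, `n_trials`.
#' @export
contact_significance <- function(onset_trains, env_list,
                                 streams = c("attended", "unattended"),
                                 n_boot = 100, n_null = 500, alpha = 0.05,
                                 duration_s = 3.18,
                                 fit_window = c(0, 2.93), fs_env = 100,
                                 n_folds = 5, ridge_lambda = 1,
                                 lag_min = 0, lag_max = 0.7,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stim <- onset_stimulus(onset_trains, streams = streams,
                         fit_window = fit_window, fs_env = fs_env)
  obs <- crossval_corr(stim, env_list, n_folds = n_folds,
                       ridge_lambda = ridge_lambda, lag_min = lag_min,
                       lag_max = lag_max, fs_env = fs_env)$mean_r
  boot <- NULL
  if (n_boot > 0)
    boot <- bootstrap_real(stim, env_list, n_boot = n_boot,
                           n_folds = n_folds, ridge_lambda = ridge_lambda,
                           lag_min = lag_min, lag_max = lag_max,
                           fs_env = fs_env)
  null <- null_distribution(onset_trains, env_list, n_null = n_null,
                            streams = streams, duration_s = duration_s,
                            fit_window = fit_window, fs_env = fs_env,
                            n_folds = n_folds, ridge_lambda = ridge_lambda,
                            lag_min = lag_min, lag_max = lag_max)
  p <- empirical_p(obs, null)
  structure(list(mean_r_observed = obs, boot_r = boot,
                 mean_r_boot = if (is.null(boot)) NA_real_ else mean(boot),
                 null_r = null, p = p, significant = p < alpha,
                 alpha = alpha, n_trials = length(env_list)),
            class = "contact_result")
}

#' Per-stream tracking analysis
#'
#' Re-runs [contact_significance()] with a single-feature stimulus matrix
#' for the requested stream.
#'
#' @param onset_trains,env_list,... as in [contact_significance()].
#' @param stream `"attended"` or `"unattended"`.
#' @return a `"contact_result"`.
#' @export
per_stream_analysis <- function(onset_trains, env_list, stream, ...) {
  if (!stream %in% c("attended", "unattended"))
    stop("unknown stream: ", stream, call. = FALSE)
  contact_significance(onset_trains, env_list, streams = stream, ...)
}

#' Cohort-level contact counting
#'
#' Counts contacts per region, the number significant at `alpha`, and the
#' percentage (rounded to the nearest integer percent, matching the
#' reporting convention where 28 of 48 is 58%).
#'
#' @param contacts data.frame with at least columns `region` and `p` (or a
#'   logical `significant`).
#' @param alpha significance level used if `significant` is absent
#'   (default 0.05).
#' @return data.frame: `region`, `n_contacts`, `n_significant`,
#'   `pct_significant`.
#' @export
aggregate_contacts <- function(contacts, alpha = 0.05) {
  if (!nrow(contacts))
    stop("empty contact table", call. = FALSE)
  sig <- if ("significant" %in% names(contacts)) contacts$significant
         else contacts$p < alpha
  region <- if ("region" %in% names(contacts)) contacts$region else "all"
  agg <- lapply(split(sig, region), function(s) {
    data.frame(n_contacts = length(s), n_significant = sum(s),
               pct_significant = round(100 * sum(s) / length(s)))
  })
  out <- do.call(rbind, agg)
  out <- cbind(region = names(agg), out)
  rownames(out) <- NULL
  out
}
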