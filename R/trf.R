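#' Build a time-lagged design matrix
#'
#' For each stimulus feature, one column per lag step over
#' `[lag_min, lag_max]`; row t of the lag-l column holds the stimulus at
#' t - l, zero-padded outside the trial. Column count is
#' `n_features * (round((lag_max - lag_min) * fs_env) + 1)`.
#'
#' @param stimulus numeric vector or samples x features matrix at `fs_env`.
#' @param lag_min,lag_max lag range in seconds (defaults 0 and 0.7).
#' @param fs_env sampling rate of the stimulus in Hz.
#' @return samples x (features * lags) matrix; columns are ordered
#'   feature-major (all lags of feature 1, then feature 2, ...).
#' @export
build_lag_matrix <- function(stimulus, lag_min = 0, lag_max = 0.7, fs_env) {
  if (!(lag_max > lag_min && lag_min >= 0))
    stop("lags must satisfy 0 <= lag_min < lag_max", call. = FALSE)
  s <- as.matrix(stimulus)
  n <- nrow(s)
  l0 <- round(lag_min * fs_env)
  n_lags <- round((lag_max - lag_min) * fs_env) + 1L
  if (l0 + n_lags - 1L >= n)
    stop("lag_max exceeds the trial length", call. = FALSE)
  cols <- lapply(seq_len(ncol(s)), function(f) {
    padded <- c(rep(0, l0 + n_lags - 1L), s[, f])
    # embed gives columns x[t], x[t-1], ..., aligned so column j is lag j-1
    stats::embed(padded, l0 + n_lags)[, (l0 + 1L):(l0 + n_lags), drop = FALSE]
  })
  do.call(cbind, cols)
}

#' Closed-form ridge regression
#'
#' Minimizes `||y - Xw||^2 + lambda ||w||^2` with an unpenalized intercept
#' handled by column/response centering, solved through the normal
#' equations.
#'
#' @param design samples x predictors matrix.
#' @param response numeric vector, one value per row of `design`.
#' @param ridge_lambda nonnegative ridge penalty.
#' @return list of class `"trf_model"`: `weights`, `intercept`,
#'   `ridge_lambda`.
#' @export
fit_ridge <- function(design, response, ridge_lambda = 1) {
  stopifnot(nrow(design) == length(response), ridge_lambda >= 0)
  xm <- colMeans(design)
  ym <- mean(response)
  Xc <- sweep(design, 2, xm)
  yc <- response - ym
  A <- crossprod(Xc)
  diag(A) <- diag(A) + ridge_lambda
  w <- tryCatch(
    solve(A, crossprod(Xc, yc)),
    error = function(e)
      stop("design is singular; use ridge_lambda > 0", call. = FALSE)
  )
  w <- drop(w)
  structure(list(weights = w, intercept = ym - sum(xm * w),
                 ridge_lambda = ridge_lambda),
            class = "trf_model")
}

#' Predict from a fitted TRF model
#'
#' `design %*% weights + intercept`; for an onset-train design this is the
#' discrete convolution of the onset impulses with the kernel plus the
#' intercept.
#'
#' @param object a `"trf_model"`.
#' @param design design matrix with the same columns the model was fit on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.trf_model <- function(object, design, ...) {
  if (ncol(design) != length(object$weights))
    stop("design does not match the fitted model", call. = FALSE)
  drop(design %*% object$weights) + object$intercept
}

# per-trial preparation shared by fitting, CV, and resampling:
# lag-expand, mean-center columns and response within trial
trial_blocks <- function(stim_list, env_list, lag_min, lag_max, fs_env) {
  stopifnot(length(stim_list) == length(env_list))
  lapply(seq_along(stim_list), function(i) {
    X <- build_lag_matrix(stim_list[[i]], lag_min, lag_max, fs_env)
    X <- sweep(X, 2, colMeans(X))
    y <- env_list[[i]] - mean(env_list[[i]])
    list(X = X, y = y, XtX = crossprod(X), Xty = crossprod(X, y),
         n = length(y))
  })
}

# ridge solve on training-fold column scaling (unit-variance predictors
# and response, lambda applied on the scaled problem), weights returned on
# the raw scale
ridge_from_blocks <- function(blocks, idx, lambda) {
  XtX <- Reduce(`+`, lapply(blocks[idx], `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(blocks[idx], `[[`, "Xty"))
  n <- sum(vapply(blocks[idx], `[[`, numeric(1), "n"))
  sy2 <- sum(vapply(blocks[idx], function(b) sum(b$y^2), numeric(1)))
  sx <- sqrt(diag(XtX) / n)
  sx[sx == 0] <- 1
  sy <- sqrt(sy2 / n)
  if (sy == 0) sy <- 1
  A <- XtX / outer(sx, sx)
  diag(A) <- diag(A) + lambda
  ws <- tryCatch(solve(A, drop(Xty) / (sx * sy)),
                 error = function(e)
                   stop("singular training design; increase ridge_lambda",
                        call. = FALSE))
  drop(ws) / sx * sy
}

# seeded contiguous-block fold assignment over trials
make_folds <- function(n_trials, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n_trials)
  sizes <- rep(n_trials %/% n_folds, n_folds)
  extra <- n_trials %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(ord, rep(seq_len(n_folds), sizes))
}

#' Fit a TRF on a full set of trials
#'
#' Ridge solution pooled over all trials with per-trial mean-centering of
#' design and response and unit-variance scaling computed on the pooled
#' data (the same scaling convention cross-validation uses).
#'
#' @param stim_list list of per-trial stimulus vectors/matrices at
#'   `fs_env`.
#' @param env_list list of matching per-trial response vectors.
#' @param ridge_lambda ridge penalty on the standardized problem
#'   (default 1).
#' @param lag_min,lag_max lag range in seconds.
#' @param fs_env sampling rate in Hz.
#' @return a `"trf_model"` whose `weights` matrix is features x lags, with
#'   `lags` (seconds) attached.
#' @export
fit_trf <- function(stim_list, env_list, ridge_lambda = 1,
                    lag_min = 0, lag_max = 0.7, fs_env) {
  blocks <- trial_blocks(stim_list, env_list, lag_min, lag_max, fs_env)
  w <- ridge_from_blocks(blocks, seq_along(blocks), ridge_lambda)
  n_feat <- ncol(as.matrix(stim_list[[1]]))
  n_lags <- length(w) / n_feat
  structure(list(
    weights = matrix(w, n_feat, n_lags, byrow = TRUE,
                     dimnames = list(colnames(as.matrix(stim_list[[1]])),
                                     NULL)),
    intercept = 0, ridge_lambda = ridge_lambda, fs_env = fs_env,
    lags = seq(lag_min, lag_max, by = 1 / fs_env)
  ), class = "trf_model")
}

#' Five-fold cross-validated TRF prediction correlation
#'
#' Trials are partitioned into folds (contiguous blocks of a seeded
#' shuffle of the trial list, so no time samples leak across the lag
#' window); the TRF is fit on the training folds and the Pearson
#' correlation computed between the concatenated held-out predictions and
#' responses; fold correlations are averaged.
#'
#' @inheritParams fit_trf
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed; `NULL` uses the current RNG state.
#' @return list of class `"cv_result"`: `fold_r`, `mean_r`, `folds`,
#'   `ridge_lambda`.
#' @export
crossval_corr <- function(stim_list, env_list, n_folds = 5,
                          ridge_lambda = 1, lag_min = 0, lag_max = 0.7,
                          fs_env, seed = NULL) {
  n_trials <- length(stim_list)
  if (n_trials < n_folds)
    stop("fewer trials than folds", call. = FALSE)
  blocks <- trial_blocks(stim_list, env_list, lag_min, lag_max, fs_env)
  folds <- make_folds(n_trials, n_folds, seed)
  fold_r <- vapply(folds, function(test_idx) {
    train_idx <- setdiff(seq_len(n_trials), test_idx)
    w <- ridge_from_blocks(blocks, train_idx, ridge_lambda)
    yhat <- unlist(lapply(blocks[test_idx], function(b) drop(b$X %*% w)))
    y <- unlist(lapply(blocks[test_idx], `[[`, "y"))
    if (stats::sd(yhat) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(yhat, y)
  }, numeric(1))
  structure(list(fold_r = unname(fold_r), mean_r = mean(fold_r),
                 folds = folds, ridge_lambda = ridge_lambda),
            class = "cv_result")
}

#' Binary onset stimulus vectors for TRF fitting
#'
#' Converts per-trial onset times (seconds relative to the target word)
#' into per-trial binary matrices at `fs_env` over a fitting window, with
#' ones at the samples nearest each onset. A 0.25 s filter-transient guard
#' is the reason the default window stops short of the sentence end.
#'
#' @param onset_trains list over trials of named lists of onset-time
#'   vectors (one per stream).
#' @param streams which streams to include as features, in order.
#' @param fit_window length-2 numeric, seconds relative to the target
#'   word (default `c(0, 2.93)`).
#' @param fs_env sampling rate in Hz.
#' @return list over trials of samples x length(streams) binary matrices.
#' @export
onset_stimulus <- function(onset_trains, streams = c("attended",
                                                     "unattended"),
                           fit_window = c(0, 2.93), fs_env) {
  n <- round((fit_window[2] - fit_window[1]) * fs_env) + 1L
  lapply(onset_trains, function(tr) {
    m <- matrix(0, n, length(streams),
                dimnames = list(NULL, streams))
    for (j in seq_along(streams)) {
      o <- tr[[streams[j]]]
      idx <- round((o - fit_window[1]) * fs_env) + 1L
      idx <- idx[idx >= 1 & idx <= n]
      m[idx, j] <- 1
    }
    m
  })
}

#' Extract per-trial envelope responses over the TRF fitting window
#'
#' @param envelope_set an `"envelope_set"` (epoch time axis relative to
#'   the target word).
#' @param channel channel index or label.
#' @param fit_window seconds relative to the target word.
#' @return list over trials of numeric response vectors.
#' @export
envelope_responses <- function(envelope_set, channel,
                               fit_window = c(0, 2.93)) {
  if (is.character(channel))
    channel <- match(channel, envelope_set$channels)
  sel <- which(envelope_set$time >= fit_window[1] - 1e-9 &
                 envelope_set$time <= fit_window[2] + 1e-9)
  lapply(seq_len(dim(envelope_set$envelope)[1]),
         function(tr) envelope_set$envelope[tr, channel, sel])
}
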