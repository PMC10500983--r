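#' Decomposition configuration
#'
#' Parameters of the convolutive blind-source-separation decomposition of
#' multichannel EMG into motor-unit pulse trains.
#'
#' @param bandpass Passband, Hz (default `c(20, 500)`).
#' @param filter_order Butterworth order (default 2; applied
#'   forward-backward, i.e., zero-phase).
#' @param target_extended Target number of extended channels; the
#'   extension factor is `ceiling(target / channels)` (default 1000).
#' @param tolerance Convergence tolerance on the change of the sparsity
#'   measure between fixed-point iterations (default 1e-4).
#' @param max_iter Maximum fixed-point iterations per run (default 100).
#' @param n_runs Number of source-extraction runs (default 50).
#' @param refine_max_iter Maximum CoV-ISI refinement iterations
#'   (default 20).
#' @param dedup_window_s Two discharges are common when within this
#'   interval after alignment, s (default 5e-4, i.e., 0.5 ms).
#' @param dedup_share Trains sharing at least this fraction of their
#'   discharges (relative to the smaller train) are duplicates
#'   (default 0.30).
#' @param dedup_max_lag_s Maximum alignment lag searched when comparing
#'   trains, s (default 0.03: extension plus action-potential
#'   propagation can offset two estimates of the same unit by tens of
#'   ms).
#' @param pnr_threshold_db Accept only trains with pulse-to-noise ratio
#'   above this, dB (default 28).
#' @param min_peak_dist_s Minimum separation of detected source peaks, s
#'   (default 0.01).
#' @param min_spikes Minimum discharges for a usable candidate
#'   (default 10).
#' @param max_rate Physiological ceiling on the mean discharge rate, 1/s
#'   (default 50).
#' @param max_cov_isi Physiological ceiling on the CoV of the interspike
#'   intervals of an accepted train (default 0.5; regular discharge is a
#'   hallmark of a correctly identified unit during isometric effort).
#' @param min_active_s Minimum active span of a candidate train, s
#'   (default 2).
#' @param reject_z Robust z-score beyond which a channel RMS marks the
#'   channel as bad during preprocessing (default 3).
#' @param seed Integer RNG seed.
#' @return An object of class `decomp_config`.
#' @export
decomp_config <- function(bandpass = c(20, 500), filter_order = 2,
                          target_extended = 1000, tolerance = 1e-4,
                          max_iter = 100, n_runs = 50, refine_max_iter = 20,
                          dedup_window_s = 5e-4, dedup_share = 0.30,
                          dedup_max_lag_s = 0.03,
                          pnr_threshold_db = 28, min_peak_dist_s = 0.01,
                          min_spikes = 10, max_rate = 50, min_active_s = 2,
                          max_cov_isi = 0.5, reject_z = 3, seed = 1) {
  stopifnot(tolerance > 0, dedup_share > 0, dedup_share < 1,
            target_extended >= 1, n_runs >= 1, max_iter >= 1)
  structure(as.list(environment()), class = "decomp_config")
}

#' Band-pass filter EMG and reject bad channels
#'
#' Zero-phase (forward-backward) Butterworth band-pass filtering of every
#' channel, followed by automated channel rejection: channels whose RMS
#' deviates by more than `reject_z` robust z-scores (median/MAD) from the
#' montage median are discarded.
#'
#' @param emg Numeric matrix `channels x samples`, or a [synthetic_emg].
#' @param fs Sampling rate, Hz (> 1000; taken from the object if given).
#' @param config A [decomp_config].
#' @return A list: `data` (filtered matrix, kept channels only), `keep`
#'   (logical mask over input channels), `fs`.
#' @export
preprocess_emg <- function(emg, fs = NULL, config = decomp_config()) {
  if (inherits(emg, "synthetic_emg")) { fs <- emg$fs; emg <- emg$data }
  if (inherits(emg, "emg_container")) { fs <- emg$fs; emg <- emg$data }
  stopifnot(is.matrix(emg), !is.null(fs))
  if (fs <= 1000) stop("'fs' must exceed 1000 Hz")
  bf <- signal::butter(config$filter_order,
                       config$bandpass / (fs / 2), type = "pass")
  filt <- t(apply(emg, 1, function(x) signal::filtfilt(bf, x)))
  rms <- sqrt(rowMeans(filt^2))
  med <- median(rms); md <- mad(rms)
  keep <- if (md > 0) abs(rms - med) / md <= config$reject_z
          else rep(TRUE, length(rms))
  if (sum(keep) < 8L)
    stop(sprintf("only %d channels survive rejection (need >= 8)", sum(keep)))
  list(data = filt[keep, , drop = FALSE], keep = keep, fs = fs)
}

#' Extend and spatially whiten multichannel EMG
#'
#' Converts the convolutive mixture into an (approximately)
#' instantaneous one by adding `R - 1` delayed copies of every channel,
#' with `R = ceiling(target / channels)` (delays `0..R-1` samples,
#' zero-padded), then whitens the extended observations by
#' eigen-decomposition of their covariance with small-eigenvalue
#' regularization: directions whose eigenvalue falls below the noise
#' floor (the mean of the smallest half of the eigenvalues) carry mostly
#' additive noise and are discarded, which keeps the whitened space
#' dominated by source activity.
#'
#' @param emg Numeric matrix `channels x samples` (typically the output
#'   of [preprocess_emg]).
#' @param target Target extended channel count (default 1000).
#' @param noise_floor Multiplier on the estimated noise floor (the mean
#'   of the smallest half of the eigenvalues); eigenvalues below
#'   `noise_floor x floor` are discarded (default 1). Larger values
#'   trade some separation detail for speed.
#' @return A list: `Z` (whitened matrix, `k x samples` on the retained
#'   subspace), `R` (extension factor), `n_extended` (`channels * R`),
#'   `eigenvalues`, `k` (retained dimension).
#' @export
extend_and_whiten <- function(emg, target = 1000, noise_floor = 1) {
  stopifnot(is.matrix(emg), nrow(emg) >= 1)
  m <- nrow(emg); n <- ncol(emg)
  R <- as.integer(ceiling(target / m))
  ext <- matrix(0, m * R, n)
  for (r in 0:(R - 1L)) {
    rows <- r * m + seq_len(m)
    if (r == 0L) ext[rows, ] <- emg
    else ext[rows, (r + 1L):n] <- emg[, seq_len(n - r), drop = FALSE]
  }
  ext <- ext - rowMeans(ext)
  C <- tcrossprod(ext) / n
  eg <- eigen(C, symmetric = TRUE)
  d <- eg$values
  lower <- d[seq.int(length(d) %/% 2 + 1L, length(d))]
  keep <- d > max(noise_floor * mean(pmax(lower, 0)), max(d) * 1e-12)
  if (!any(keep)) stop("degenerate covariance: no retained directions")
  W <- t(eg$vectors[, keep, drop = FALSE]) / sqrt(d[keep])
  Z <- W %*% ext
  list(Z = Z, R = R, n_extended = m * R, eigenvalues = d, k = sum(keep))
}

cov_isi <- function(times) {
  if (length(times) < 3) return(NA_real_)
  isi <- diff(times)
  sd(isi) / mean(isi)
}

# peak detection on the squared source with a minimum peak distance,
# followed by 2-class K-means on the peak amplitudes; returns sample
# indices of the high-amplitude class.
detect_spikes <- function(s, fs, min_peak_dist_s = 0.01) {
  s2 <- s^2
  d <- diff(s2)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(pk) < 2L) return(integer(0))
  # enforce minimum distance, keeping higher peaks first
  mind <- max(1L, as.integer(round(min_peak_dist_s * fs)))
  ord <- pk[order(s2[pk], decreasing = TRUE)]
  taken <- logical(length(s))
  sel <- integer(0)
  for (p in ord) {
    if (!taken[p]) {
      sel <- c(sel, p)
      lo <- max(1L, p - mind); hi <- min(length(s), p + mind)
      taken[lo:hi] <- TRUE
    }
  }
  sel <- sort(sel)
  h <- s2[sel]
  if (length(unique(h)) < 2L) return(sel)
  km <- suppressWarnings(
    kmeans(h, centers = matrix(c(min(h), max(h)), 2, 1), iter.max = 100))
  hi_cl <- which.max(km$centers)
  sel[km$cluster == hi_cl]
}

#' Extract one candidate motor-unit pulse train
#'
#' One run of the fixed-point source-extraction algorithm on the
#' whitened extended observations: the separation vector is initialized
#' at the time sample of highest extended-signal activity not yet used,
#' updated with the log-cosh contrast (`g' = tanh`, `g'' = 1 - tanh^2`),
#' deflation-orthogonalized against previously accepted vectors and
#' unit-normalized, until the sparsity measure (mean `log cosh` of the
#' source) changes by less than the tolerance. The pulse train is the
#' signed-squared projection `s * |s|` (squaring skews the distribution
#' toward zero and sharpens the discharge peaks, the convention of this
#' algorithm family); discharges are the high-amplitude class of a
#' 2-class K-means over its peaks.
#'
#' @param Z Whitened matrix from [extend_and_whiten].
#' @param fs Sampling rate, Hz.
#' @param prior Matrix whose columns are previously found (orthonormal)
#'   separation vectors, or `NULL`.
#' @param init_sample Initialization sample index; default the argmax of
#'   the summed squared whitened signal.
#' @param config A [decomp_config].
#' @return An object of class `pulse_train`: `times` (s), `spikes`
#'   (sample indices), `w` (separation vector), `source`, `pnr`,
#'   `cov_isi`, `converged`, `n_iter`.
#' @export
extract_source <- function(Z, fs, prior = NULL, init_sample = NULL,
                           config = decomp_config()) {
  stopifnot(is.matrix(Z))
  n <- ncol(Z)
  if (is.null(init_sample)) init_sample <- which.max(colSums(Z^2))
  w <- Z[, init_sample]
  deflate <- function(v) {
    if (!is.null(prior) && ncol(prior) > 0) v <- v - prior %*% crossprod(prior, v)
    v / sqrt(sum(v^2))
  }
  w <- deflate(w)
  sp_old <- Inf; converged <- FALSE; it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    s <- as.numeric(crossprod(w, Z))
    sp <- mean(log(cosh(s)))   # sparsity of the current iterate
    if (is.finite(sp_old) && abs(sp - sp_old) < config$tolerance) {
      converged <- TRUE
      break
    }
    sp_old <- sp
    th <- tanh(s)
    w_new <- (Z %*% th) / n - mean(1 - th^2) * w
    w <- deflate(as.numeric(w_new))
  }
  s <- as.numeric(crossprod(w, Z))
  if (sum(s^3) < 0) { s <- -s; w <- -w }   # orient spikes upward
  spikes <- detect_spikes(s, fs, config$min_peak_dist_s)
  times <- (spikes - 1L) / fs
  src <- s * abs(s)   # signed-squared pulse train
  structure(list(times = times, spikes = spikes, w = w, source = src,
                 pnr = if (length(spikes)) pnr_from_source(src, spikes) else NA_real_,
                 cov_isi = cov_isi(times), converged = converged,
                 n_iter = it, init_sample = init_sample),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %d discharges, PNR %.1f dB, CoV-ISI %.2f%s\n",
    length(x$times), x$pnr, x$cov_isi,
    if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Refine a pulse train by minimizing the CoV of interspike intervals
#'
#' Iteratively recalculates the motor-unit filter as the mean of the
#' whitened observation columns at the current discharge instants,
#' reprojects, re-detects discharges, and accepts the iterate only while
#' the coefficient of variation of the interspike intervals decreases
#' (at most `refine_max_iter` iterations).
#'
#' @param train A [extract_source] result with at least 4 discharges
#'   (fewer: returned unchanged with `refined = FALSE`).
#' @param Z Whitened matrix.
#' @param fs Sampling rate, Hz.
#' @param config A [decomp_config].
#' @return A refined `pulse_train` (field `refined = TRUE` and
#'   `cov_history` recording the accepted CoV-ISI sequence).
#' @export
refine_by_cov <- function(train, Z, fs, config = decomp_config()) {
  if (length(train$spikes) < 4L) {
    train$refined <- FALSE
    return(train)
  }
  best <- train
  best_cov <- if (is.finite(train$cov_isi)) train$cov_isi else Inf
  hist <- best_cov
  spikes <- train$spikes
  for (it in seq_len(config$refine_max_iter)) {
    w <- rowMeans(Z[, spikes, drop = FALSE])
    w <- w / sqrt(sum(w^2))
    s <- as.numeric(crossprod(w, Z))
    if (sum(s^3) < 0) { s <- -s; w <- -w }
    spikes <- detect_spikes(s, fs, config$min_peak_dist_s)
    if (length(spikes) < 4L) break
    cv <- cov_isi((spikes - 1L) / fs)
    if (!is.finite(cv) || cv >= best_cov) break
    best_cov <- cv
    hist <- c(hist, cv)
    src <- s * abs(s)
    best <- structure(list(times = (spikes - 1L) / fs, spikes = spikes,
                           w = w, source = src,
                           pnr = pnr_from_source(src, spikes),
                           cov_isi = cv, converged = train$converged,
                           n_iter = train$n_iter,
                           init_sample = train$init_sample),
                      class = "pulse_train")
  }
  best$refined <- TRUE
  best$cov_history <- hist
  best
}

# recompute the unit filter from the current discharges and keep the
# iterate while the PNR improves (filter updates from corrected
# discharge times reliably sharpen the pulse train)
polish_by_pnr <- function(train, Z, fs, config, max_polish = 10L) {
  if (length(train$spikes) < 4L) return(train)
  for (i in seq_len(max_polish)) {
    w <- rowMeans(Z[, train$spikes, drop = FALSE])
    w <- w / sqrt(sum(w^2))
    s <- as.numeric(crossprod(w, Z))
    if (sum(s^3) < 0) { s <- -s; w <- -w }
    sp <- detect_spikes(s, fs, config$min_peak_dist_s)
    if (length(sp) < 4L) break
    src <- s * abs(s)
    p <- pnr_from_source(src, sp)
    if (!is.finite(p) || p <= train$pnr) break
    train <- structure(list(times = (sp - 1L) / fs, spikes = sp, w = w,
                            source = src, pnr = p,
                            cov_isi = cov_isi((sp - 1L) / fs),
                            converged = train$converged,
                            n_iter = train$n_iter,
                            refined = train$refined,
                            cov_history = train$cov_history),
                       class = "pulse_train")
  }
  train
}

pnr_from_source <- function(s, spike_idx) {
  ps <- mean(s[spike_idx]^2)
  pn <- mean(s[-spike_idx]^2)
  if (pn <= 0) return(Inf)
  10 * log10(ps / pn)
}

#' Pulse-to-noise ratio of a source
#'
#' `10 log10` of the ratio between the mean squared series at the
#' discharge samples and at all other samples; the standard
#' decomposition-accuracy proxy. For decomposition output the series is
#' the signed-squared pulse train (see [extract_source]), matching the
#' convention under which the 28-dB acceptance threshold is defined. A
#' zero baseline returns `Inf` (saturated).
#'
#' @param source Numeric source series.
#' @param spike_times Discharge times, s (at least one).
#' @param fs Sampling rate, Hz.
#' @return PNR in dB.
#' @export
pnr <- function(source, spike_times, fs) {
  if (length(spike_times) < 1) stop("need at least one discharge")
  idx <- pmin(pmax(round(spike_times * fs) + 1L, 1L), length(source))
  pnr_from_source(source, unique(idx))
}

# greedy one-to-one count of |a - b| <= tol matches between sorted vectors
match_count <- function(a, b, tol) {
  i <- 1L; j <- 1L; m <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) { m <- m + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) i <- i + 1L
    else j <- j + 1L
  }
  m
}

# best common-discharge count between two trains over alignment lags
best_common <- function(ta, tb, tol, max_lag_s = 0.01, lag_step = tol) {
  lags <- seq(-max_lag_s, max_lag_s, by = lag_step)
  best <- 0L; best_lag <- 0
  for (l in lags) {
    m <- match_count(ta, tb + l, tol)
    if (m > best) { best <- m; best_lag <- l }
  }
  list(common = best, lag = best_lag)
}

#' Remove duplicate motor-unit pulse trains
#'
#' Pairs of trains are aligned by the lag maximizing their number of
#' common discharges (cross-correlation of the discharge trains);
#' discharges within `window_s` are common, and trains sharing at least
#' `share` of the smaller train's discharges form a duplicate group, of
#' which only the member with the lowest CoV-ISI is retained.
#'
#' @param trains List of `pulse_train` objects.
#' @param window_s Common-discharge window, s (default 5e-4).
#' @param share Duplicate share threshold (default 0.30).
#' @param max_lag_s Maximum alignment lag, s (default 0.01).
#' @return A list: `trains` (survivors), `removed` (count),
#'   `groups` (duplicate group index per input train).
#' @export
remove_duplicates <- function(trains, window_s = 5e-4, share = 0.30,
                              max_lag_s = 0.01) {
  n <- length(trains)
  if (n <= 1L) return(list(trains = trains, removed = 0L,
                           groups = seq_len(n)))
  dup <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ta <- trains[[i]]$times; tb <- trains[[j]]$times
    if (!length(ta) || !length(tb)) next
    bc <- best_common(ta, tb, window_s, max_lag_s)
    if (bc$common / min(length(ta), length(tb)) >= share)
      dup[i, j] <- dup[j, i] <- TRUE
  }
  # connected components of the duplicate graph
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(dup[i, ])
      if (length(nb)) {
        g <- min(grp[c(i, nb)])
        if (any(grp[c(i, nb)] != g)) { grp[c(i, nb)] <- g; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  keep <- logical(n)
  for (g in unique(grp)) {
    mem <- which(grp == g)
    cv <- vapply(mem, function(k) {
      v <- trains[[k]]$cov_isi
      if (is.finite(v)) v else Inf
    }, numeric(1))
    keep[mem[which.min(cv)]] <- TRUE
  }
  list(trains = trains[keep], removed = sum(!keep), groups = grp)
}

#' Decompose multichannel EMG into motor-unit pulse trains
#'
#' The full convolutive blind-source-separation pipeline: band-pass
#' filtering and channel rejection, extension and whitening, repeated
#' fixed-point source extraction (initialized at successive unused
#' activity maxima, deflated against previous sources), CoV-ISI
#' refinement, physiological gating (mean rate, active span), the
#' pulse-to-noise-ratio gate, and duplicate removal. In `"quadrants"`
#' mode, the montage is split into its four sub-grids, each decomposed
#' independently, and duplicates are removed across sub-grids.
#'
#' @param emg A [synthetic_emg], [emg_container], or numeric matrix
#'   `channels x samples` (then `fs` is required).
#' @param grid A [grid_spec] matching the channels (required for
#'   `"quadrants"` mode).
#' @param config A [decomp_config].
#' @param mode `"whole"` (default) or `"quadrants"`.
#' @param fs Sampling rate, Hz, when `emg` is a bare matrix.
#' @return An object of class `decomposition_result`: `trains` (accepted
#'   [extract_source] trains with fields `pnr`, `cov_isi`, `origin`),
#'   `rejected` (named counts by reason), `channel_keep`, `config`,
#'   `mode`.
#' @export
decompose <- function(emg, grid = NULL, config = decomp_config(),
                      mode = c("whole", "quadrants"), fs = NULL) {
  mode <- match.arg(mode)
  if (inherits(emg, "synthetic_emg") || inherits(emg, "emg_container")) {
    fs <- emg$fs
    if (is.null(grid)) grid <- emg$grid
    emg <- emg$data
  }
  stopifnot(is.matrix(emg), !is.null(fs))
  if (!is.null(grid) && nrow(emg) != grid$n)
    stop(sprintf("EMG has %d channels but grid has %d electrodes",
                 nrow(emg), grid$n))
  if (mode == "quadrants") {
    if (is.null(grid)) stop("'quadrants' mode requires a grid")
    quads <- split_quadrants(grid)
    trains <- list()
    rejected <- c(not_converged = 0L, too_few_spikes = 0L,
                  unphysiological = 0L, low_pnr = 0L, duplicate = 0L)
    keeps <- list()
    for (q in seq_along(quads)) {
      cmap <- attr(quads[[q]], "channel_map")
      sub <- decompose(emg[cmap, , drop = FALSE], grid = quads[[q]],
                       config = config, mode = "whole", fs = fs)
      for (tr in sub$trains) {
        tr$origin <- sprintf("quadrant_%d", q)
        trains[[length(trains) + 1L]] <- tr
      }
      rejected <- rejected + sub$rejected
      keeps[[q]] <- sub$channel_keep
    }
    R_q <- ceiling(config$target_extended /
                     max(1L, length(attr(quads[[1]], "channel_map"))))
    dd <- remove_duplicates(trains, config$dedup_window_s,
                            config$dedup_share,
                            config$dedup_max_lag_s + R_q / fs)
    rejected["duplicate"] <- rejected["duplicate"] + dd$removed
    return(structure(list(trains = dd$trains, rejected = rejected,
                          channel_keep = keeps, config = config,
                          mode = mode),
                     class = "decomposition_result"))
  }
  pp <- preprocess_emg(emg, fs = fs, config = config)
  ew <- extend_and_whiten(pp$data, target = config$target_extended)
  Z <- ew$Z
  n <- ncol(Z)
  activity <- colSums(Z^2)
  excl_w <- max(1L, as.integer(round(0.01 * fs)))
  used <- logical(n)
  B <- NULL
  # remove a found train's mean delayed embedding from the whitened data
  # ("peel-off"), so later runs converge to the remaining units instead
  # of re-extracting a lagged copy of the same one
  peel_ds <- seq.int(-4L, as.integer(round(0.03 * fs)) + ew$R + 4L)
  peel_train <- function(train, mark_used = TRUE) {
    for (d in peel_ds) {
      idx <- train$spikes + d
      idx <- idx[idx >= 1L & idx <= n]
      if (length(idx) < 2L) next
      sig <- rowMeans(Z[, idx, drop = FALSE])
      Z[, idx] <<- Z[, idx] - sig
    }
    touched <- unique(pmin(pmax(rep(train$spikes,
                                    each = length(peel_ds)) +
                                peel_ds, 1L), n))
    activity[touched] <<- colSums(Z[, touched, drop = FALSE]^2)
    if (mark_used)
      used[pmin(pmax(rep(train$spikes, each = 2L * excl_w + 1L) +
                       (-excl_w):excl_w, 1L), n)] <<- TRUE
  }
  cand <- list()
  rejected <- c(not_converged = 0L, too_few_spikes = 0L,
                unphysiological = 0L, low_pnr = 0L, duplicate = 0L)
  with_seed(config$seed, {
    for (run in seq_len(config$n_runs)) {
      act <- activity
      act[used] <- -Inf
      t0 <- which.max(act)
      if (!is.finite(act[t0])) break
      used[max(1L, t0 - excl_w):min(n, t0 + excl_w)] <- TRUE
      tr <- extract_source(Z, fs, prior = B, init_sample = t0,
                           config = config)
      if (!tr$converged) { rejected["not_converged"] <-
                             rejected["not_converged"] + 1L; next }
      if (length(tr$spikes) < config$min_spikes) {
        B <- cbind(B, tr$w)   # deflate later runs from this direction
        rejected["too_few_spikes"] <- rejected["too_few_spikes"] + 1L
        next
      }
      tr <- refine_by_cov(tr, Z, fs, config)
      tr <- polish_by_pnr(tr, Z, fs, config)
      span <- diff(range(tr$times))
      rate <- length(tr$times) / max(span, 1e-9)
      if (length(tr$spikes) < config$min_spikes || span < config$min_active_s ||
          rate > config$max_rate ||
          !is.finite(tr$cov_isi) || tr$cov_isi > config$max_cov_isi) {
        B <- cbind(B, tr$w)
        rejected["unphysiological"] <- rejected["unphysiological"] + 1L
        next
      }
      peel_train(tr)   # plausibly a real unit: remove it from the mix
      if (!is.finite(tr$pnr) || tr$pnr > config$pnr_threshold_db) {
        tr$origin <- "whole"
        cand[[length(cand) + 1L]] <- tr
      } else {
        rejected["low_pnr"] <- rejected["low_pnr"] + 1L
      }
    }
  })
  # two estimates of one unit can sit R samples apart in the extended
  # space, so the alignment search grows with the extension factor
  dd <- remove_duplicates(cand, config$dedup_window_s, config$dedup_share,
                          config$dedup_max_lag_s + ew$R / fs)
  rejected["duplicate"] <- dd$removed
  structure(list(trains = dd$trains, rejected = rejected,
                 channel_keep = pp$keep, config = config, mode = mode),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("EMG decomposition (%s mode): %d accepted motor units\n",
              x$mode, length(x$trains)))
  if (length(x$trains)) {
    pnrs <- vapply(x$trains, `[[`, numeric(1), "pnr")
    cat(sprintf("  PNR %.1f-%.1f dB; rejected: %s\n",
                min(pnrs), max(pnrs),
                paste(names(x$rejected), x$rejected, sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.decomposition_result <- function(object, ...) {
  data.frame(
    unit = seq_along(object$trains),
    n_discharges = vapply(object$trains, function(t) length(t$times),
                          integer(1)),
    pnr_db = vapply(object$trains, `[[`, numeric(1), "pnr"),
    cov_isi = vapply(object$trains, `[[`, numeric(1), "cov_isi"),
    origin = vapply(object$trains, function(t)
      if (is.null(t$origin)) "whole" else t$origin, character(1)))
}
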