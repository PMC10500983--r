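#' Force recruitment-threshold law of the motor-unit pool
#'
#' Recruitment threshold (% MVC) of the motor unit at normalized pool
#' rank `j` in `[0, 1]` (ranked in ascending threshold order), following
#' the frequency distribution of recruitment thresholds typical of the
#' human tibialis anterior:
#' `Fth(j) = 0.50 * (58.12 * j + 120 * j^1.83)`.
#'
#' @param j Normalized pool rank(s) in `[0, 1]`.
#' @return Recruitment threshold(s), % MVC (0 at `j = 0`, 89.06 at
#'   `j = 1`).
#' @examples
#' fth(c(0, 0.5, 1))
#' @export
fth <- function(j) {
  if (any(j < 0 | j > 1)) stop("'j' must lie in [0, 1]")
  0.50 * (58.12 * j + 120 * j^1.83)
}

#' Invert the recruitment-threshold law
#'
#' Finds `j` such that `fth(j) = F` by bisection (monotone law), to an
#' absolute tolerance of 1e-9 on `fth`.
#'
#' @param F Threshold(s), % MVC, within `[0, fth(1)]`.
#' @return Normalized pool rank(s) in `[0, 1]`.
#' @examples
#' invert_fth(fth(0.3))  # 0.3
#' @export
invert_fth <- function(F) {
  if (any(F < 0 | F > fth(1) + 1e-12)) stop("'F' outside [0, fth(1)]")
  vapply(F, function(f) {
    if (f <= 0) return(0)
    lo <- 0; hi <- 1
    while (fth(hi) - fth(lo) > 1e-10 && hi - lo > 1e-15) {
      mid <- (lo + hi) / 2
      if (fth(mid) < f) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Trapezoidal isometric force profile
#'
#' Linear ramp up at `ramp` %/s, plateau at `target` % MVC for
#' `plateau_s` seconds, linear ramp down at the same rate.
#'
#' @param target Plateau force, % MVC (> 0).
#' @param plateau_s Plateau duration, s.
#' @param ramp Ramp rate, %/s (default 5).
#' @param fs Sampling rate, Hz (default 2048).
#' @return An object of class `force_profile`: `force` (% MVC per
#'   sample), `fs`, `target`, `ramp`, `plateau_s`, `duration_s`.
#' @examples
#' trapezoid_profile(30, 20)$duration_s  # 6 + 20 + 6 = 32 s
#' @export
trapezoid_profile <- function(target, plateau_s, ramp = 5, fs = 2048) {
  if (target <= 0 || ramp <= 0) stop("'target' and 'ramp' must be positive")
  stopifnot(plateau_s >= 0, fs > 0)
  t_ramp <- target / ramp
  duration <- 2 * t_ramp + plateau_s
  tt <- seq(0, duration, by = 1 / fs)
  force <- pmin(pmin(tt, duration - tt) * ramp, target)
  force <- pmax(pmin(force, target), 0)
  structure(list(force = force, fs = fs, target = target, ramp = ramp,
                 plateau_s = plateau_s, duration_s = duration),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("Trapezoidal force profile: %g%% MVC, %g%%/s ramps, %g s plateau (%g s total, %g Hz)\n",
              x$target, x$ramp, x$plateau_s, x$duration_s, x$fs))
  invisible(x)
}

#' @export
plot.force_profile <- function(x, ...) {
  tt <- (seq_along(x$force) - 1) / x$fs
  plot(tt, x$force, type = "l", xlab = "time (s)", ylab = "force (% MVC)", ...)
  invisible(x)
}

#' Simulate motor-unit discharge trains for a force profile
#'
#' Each of `n_units` units receives a recruitment threshold from the
#' [fth] law at its normalized rank. A unit discharges only while the
#' force is at or above its threshold, at an instantaneous rate
#' `min(rate_min + gain * (force - threshold), rate_max)` discharges/s;
#' interspike intervals are jittered with Gaussian noise of coefficient
#' of variation `isi_cov`. Rates are capped below 50/s, the physiological
#' ceiling during submaximal isometric contractions.
#'
#' @param profile A [trapezoid_profile] (or compatible) force profile.
#' @param n_units Pool size.
#' @param rate_min Discharge rate at recruitment, 1/s (default 8).
#' @param rate_max Rate ceiling, 1/s (default 35; must be < 50).
#' @param gain Rate gain, (1/s) per % MVC above threshold (default 0.3).
#' @param isi_cov Coefficient of variation of the interspike-interval
#'   jitter (default 0.15; 0 gives perfectly regular firing).
#' @param seed Integer RNG seed.
#' @return An object of class `spike_train_set`: `times` (list of
#'   strictly increasing discharge-time vectors, s), `threshold`
#'   (recruitment thresholds, % MVC), `j` (normalized ranks), `early`
#'   (ground-truth early/late-recruited label relative to the profile
#'   target), `fs`, `duration_s`, `seed`.
#' @export
simulate_discharges <- function(profile, n_units, rate_min = 8,
                                rate_max = 35, gain = 0.3, isi_cov = 0.15,
                                seed = 1) {
  stopifnot(inherits(profile, "force_profile") || is.list(profile))
  if (rate_max >= 50) stop("'rate_max' must stay below 50/s")
  stopifnot(rate_min > 0, rate_min <= rate_max, gain >= 0, isi_cov >= 0)
  j <- if (n_units == 1L) 0 else (seq_len(n_units) - 1) / (n_units - 1)
  thr <- fth(j)
  jstar <- invert_fth(min(profile$target, fth(1)))
  early <- j <= jstar / 2
  force_at <- function(t) {
    idx <- pmin(pmax(floor(t * profile$fs) + 1, 1), length(profile$force))
    profile$force[idx]
  }
  dur <- profile$duration_s
  times <- vector("list", n_units)
  with_seed(seed, {
    for (i in seq_len(n_units)) {
      if (thr[i] > profile$target) { times[[i]] <- numeric(0); next }
      # recruitment: first sampled instant at/above the threshold
      t <- ceiling(thr[i] / profile$ramp * profile$fs) / profile$fs
      spk <- numeric(0)
      while (t <= dur && force_at(t) >= thr[i] - 1e-9) {
        spk <- c(spk, t)
        rate <- min(rate_min + gain * (force_at(t) - thr[i]), rate_max)
        isi <- (1 / rate) * (1 + isi_cov * rnorm(1))
        isi <- max(isi, 1 / 49.9, 0.25 / rate)  # keep rate < 50/s
        t <- t + isi
      }
      times[[i]] <- spk
    }
  })
  structure(list(times = times, threshold = thr, j = j, early = early,
                 fs = profile$fs, duration_s = dur, target = profile$target,
                 seed = seed),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  act <- sum(lengths(x$times) > 0)
  cat(sprintf(
    "Spike-train set: %d units (%d active), %.1f s, %d discharges total\n",
    length(x$times), act, x$duration_s, sum(lengths(x$times))))
  invisible(x)
}

#' Render noisy multichannel surface EMG from MUAPs and spike trains
#'
#' Each channel is the sum over units of the unit's spike train convolved
#' with its MUAP waveform at that channel, plus band-limited
#' (20-500 Hz) Gaussian noise scaled so the overall signal-to-noise
#' ratio equals `snr_db` (use `Inf` for noise-free).
#'
#' @param muaps A [compute_muaps] result; `muaps$fs` must equal the
#'   spike-train sampling rate.
#' @param trains A [simulate_discharges] result (units in the same order
#'   as `muaps`).
#' @param snr_db Total signal-to-noise ratio, dB (default 20).
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `synthetic_emg`: `data` (matrix
#'   `channels x samples`, uV), `fs`, `grid`, `snr_db`, and
#'   `ground_truth` (the spike trains and the MUAP set).
#' @export
render_emg <- function(muaps, trains, snr_db = 20, seed = 1) {
  stopifnot(inherits(muaps, "muap_set"), inherits(trains, "spike_train_set"))
  if (muaps$fs != trains$fs)
    stop("sampling rates of MUAPs and spike trains differ")
  if (dim(muaps$waveforms)[1] != length(trains$times))
    stop("unit counts of MUAPs and spike trains differ")
  fs <- muaps$fs
  nt <- dim(muaps$waveforms)[3]
  nch <- dim(muaps$waveforms)[2]
  nsamp <- as.integer(ceiling(trains$duration_s * fs)) + nt
  emg <- matrix(0, nch, nsamp)
  for (i in seq_along(trains$times)) {
    spk <- trains$times[[i]]
    if (!length(spk)) next
    w <- muaps$waveforms[i, , , drop = TRUE]
    if (nch == 1L) w <- matrix(w, nrow = 1)
    idx0 <- round(spk * fs)
    for (s in idx0) {
      cols <- (s + 1L):(s + nt)
      keep <- cols <= nsamp & cols >= 1L
      emg[, cols[keep]] <- emg[, cols[keep]] + w[, keep, drop = FALSE]
    }
  }
  if (is.finite(snr_db)) {
    p_sig <- mean(emg^2)
    with_seed(seed, {
      noise <- matrix(rnorm(nch * nsamp), nch, nsamp)
    })
    bf <- signal::butter(2, c(20, 500) / (fs / 2), type = "pass")
    for (c in seq_len(nch))
      noise[c, ] <- signal::filter(bf, noise[c, ])
    p_noise <- mean(noise^2)
    target <- p_sig / 10^(snr_db / 10)
    if (p_noise > 0) emg <- emg + noise * sqrt(target / p_noise)
  }
  structure(list(data = emg, fs = fs, grid = muaps$grid, snr_db = snr_db,
                 ground_truth = list(trains = trains, muaps = muaps)),
            class = "synthetic_emg")
}

#' @export
print.synthetic_emg <- function(x, ...) {
  cat(sprintf("Synthetic EMG: %d channels x %d samples (%g Hz, SNR %g dB)\n",
              nrow(x$data), ncol(x$data), x$fs, x$snr_db))
  invisible(x)
}
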