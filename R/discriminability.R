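#' Discriminability analysis configuration
#'
#' @param nmsd_threshold Pairs of multichannel MUAPs with aligned
#'   normalized mean-square difference (NMSD) below this fraction are
#'   considered not discriminable (default 0.05, i.e., 5%).
#' @param max_lag_ms Maximum alignment lag searched by cross-correlation,
#'   ms (default 10).
#' @param normalization Denominator of the NMSD: `"mean"` (mean of the
#'   two waveform energies; symmetric and scale-balanced, the default) or
#'   `"max"` (the larger energy).
#' @return An object of class `discriminability_config`.
#' @export
discriminability_config <- function(nmsd_threshold = 0.05, max_lag_ms = 10,
                                    normalization = c("mean", "max")) {
  stopifnot(nmsd_threshold > 0, nmsd_threshold < 1, max_lag_ms >= 0)
  structure(list(nmsd_threshold = nmsd_threshold, max_lag_ms = max_lag_ms,
                 normalization = match.arg(normalization)),
            class = "discriminability_config")
}

# summed (over channels) linear cross-correlation of two channels x samples
# matrices for integer lags -L..L, treating signals as zero outside their
# window. cc[k] = sum_t a[t] b[t + lags[k]]: a positive lag means b is
# delayed relative to a by that many samples.
xcorr_sum <- function(a, b, L) {
  ns <- ncol(a)
  if (L == 0) return(list(lags = 0L, cc = sum(a * b)))
  nfft <- nextn(ns + L, 2)
  pa <- matrix(0, nfft, nrow(a)); pa[seq_len(ns), ] <- t(a)
  pb <- matrix(0, nfft, nrow(b)); pb[seq_len(ns), ] <- t(b)
  S <- rowSums(Conj(mvfft(pa)) * mvfft(pb))
  cc_full <- Re(fft(S, inverse = TRUE)) / nfft   # cc_full[m+1] = sum a[t] b[t+m]
  lags <- (-L):L
  idx <- ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)
  list(lags = lags, cc = cc_full[idx])
}

#' Align two multichannel waveforms and compute their NMSD
#'
#' Finds the single global integer lag (shared by all channels, so that
#' inter-electrode delay differences remain informative) maximizing the
#' magnitude of the summed cross-correlation across channels, then
#' computes the normalized mean-square difference between the aligned
#' waveforms:
#' `nmsd = sum((a - shift(b))^2) / denom`, where the shifted-out part of
#' `b` is zero-padded and `denom` is the mean (or max) of the two total
#' energies.
#'
#' @param a,b Numeric matrices `channels x samples` with equal channel
#'   counts and sampling rate.
#' @param fs Sampling rate, Hz.
#' @param max_lag_ms Maximum lag searched, ms (default 10).
#' @param normalization `"mean"` (default) or `"max"`; see
#'   [discriminability_config].
#' @return A list with `lag` (samples; positive means `b` is delayed to
#'   match `a`), `lag_ms`, and `nmsd` (fraction; 0 for identical
#'   waveforms, ~4 for sign-flipped ones).
#' @examples
#' a <- matrix(sin(seq(0, 6 * pi, length.out = 64)), 1)
#' align_and_nmsd(a, 1.1 * a, fs = 2048)$nmsd  # about 0.009
#' @export
align_and_nmsd <- function(a, b, fs, max_lag_ms = 10,
                           normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop("'a' and 'b' must have the same channel count and length")
  L <- as.integer(round(max_lag_ms * fs / 1000))
  ea <- sum(a^2); eb <- sum(b^2)
  denom <- if (normalization == "mean") (ea + eb) / 2 else max(ea, eb)
  if (denom == 0) return(list(lag = 0L, lag_ms = 0, nmsd = 0))
  xc <- xcorr_sum(a, b, L)
  k <- which.max(abs(xc$cc))
  lag <- xc$lags[k]
  nmsd <- (ea + eb - 2 * xc$cc[k]) / denom
  list(lag = lag, lag_ms = lag / fs * 1000, nmsd = max(nmsd, 0))
}

# core identifiability computation on a waveform array [units x elec x nt].
# Uses an exact energy lower bound on the NMSD (Cauchy-Schwarz:
# C(lag) <= sqrt(Ea Eb)) to skip pairs that cannot fall below threshold.
identifiable_from_array <- function(wav, fs, config) {
  nu <- dim(wav)[1]
  if (nu == 1L) return(TRUE)
  thr <- config$nmsd_threshold
  L <- as.integer(round(config$max_lag_ms * fs / 1000))
  ns <- dim(wav)[3]
  nfft <- nextn(ns + L, c(2, 3))
  # per-channel energies: the summed cross-correlation at any lag is
  # bounded by sum_c sqrt(Ea_c * Eb_c) (Cauchy-Schwarz per channel), so
  # most pairs can be declared discriminable without any alignment
  nch <- dim(wav)[2]
  Ech <- matrix(vapply(seq_len(nu), function(i)
    rowSums(matrix(wav[i, , ], nrow = nch)^2), numeric(nch)), nrow = nch)
  E <- colSums(Ech)
  Cmax <- crossprod(sqrt(Ech))                      # nu x nu bound on C*
  cache <- vector("list", nu)
  get_fft <- function(i) {
    if (is.null(cache[[i]])) {
      p <- matrix(0, nfft, dim(wav)[2])
      p[seq_len(ns), ] <- t(wav[i, , , drop = TRUE])
      cache[[i]] <<- mvfft(p)
    }
    cache[[i]]
  }
  lag_idx <- {
    lags <- (-L):L
    ifelse(-lags >= 0, -lags + 1L, nfft + (-lags) + 1L)
  }
  ident <- rep(TRUE, nu)
  for (i in seq_len(nu - 1L)) {
    for (j in (i + 1L):nu) {
      ea <- E[i]; eb <- E[j]
      denom <- if (config$normalization == "mean") (ea + eb) / 2
               else max(ea, eb)
      if (denom == 0) { ident[i] <- ident[j] <- FALSE; next }
      bound <- (ea + eb - 2 * Cmax[i, j]) / denom
      if (bound >= thr) next
      S <- rowSums(Conj(get_fft(i)) * get_fft(j))
      cc <- Re(fft(S, inverse = TRUE))[lag_idx] / nfft
      cstar <- cc[which.max(abs(cc))]
      nmsd <- max((ea + eb - 2 * cstar) / denom, 0)
      if (nmsd < thr) ident[i] <- ident[j] <- FALSE
    }
  }
  ident
}

#' Theoretically identifiable motor units of a MUAP set
#'
#' A unit is theoretically identifiable when its multichannel MUAP
#' differs from every other unit's (aligned NMSD at or above the
#' threshold, default 5%): the algorithm-independent upper bound on the
#' units any decomposition can separate. A single-unit pool is
#' identifiable by convention (vacuous pairwise test).
#'
#' @param muaps A [compute_muaps] result (or compatible list with
#'   `waveforms` and `fs`).
#' @param config A [discriminability_config].
#' @return Logical vector, one flag per unit.
#' @export
identifiable_set <- function(muaps, config = discriminability_config()) {
  stopifnot(!is.null(muaps$waveforms), !is.null(muaps$fs))
  if (dim(muaps$waveforms)[1] < 1L) stop("need at least 1 unit")
  identifiable_from_array(muaps$waveforms, muaps$fs, config)
}

#' Default grid-design sweep configurations
#'
#' The 84 simulated grid configurations: 7 grid lengths (4-10 cm at
#' 3.6-cm width, covering 14.4-36 cm^2) crossed with 12 interelectrode
#' distances from 2 to 36 mm.
#'
#' @param lengths_cm Grid lengths, cm.
#' @param ieds_mm Interelectrode distances, mm.
#' @param width_cm Grid width, cm.
#' @return A data.frame with columns `length_cm`, `ied_mm`, `width_cm`.
#' @export
default_sweep_configs <- function(lengths_cm = 4:10,
                                  ieds_mm = c(2, 4, 6, 8, 10, 12, 16, 20,
                                              24, 28, 32, 36),
                                  width_cm = 3.6) {
  out <- expand.grid(length_cm = lengths_cm, ied_mm = ieds_mm)
  out$width_cm <- width_cm
  out
}

#' Sweep grid configurations and record theoretical identifiability
#'
#' For each `(length, IED)` configuration, builds the simulated grid,
#' computes the pool's multichannel MUAPs, and records the percentage of
#' theoretically identifiable units and the depth statistics of the
#' identifiable units. MUAPs are computed once on the union of all
#' electrode positions and re-used across configurations.
#'
#' @param pool A [build_pool] result.
#' @param configs Data.frame with `length_cm`, `ied_mm` and optionally
#'   `width_cm` (default 3.6); see [default_sweep_configs].
#' @param fs,window_ms,tissue,fiber_subsample,dz,seed Forwarded to
#'   [compute_muaps].
#' @param config A [discriminability_config].
#' @return An object of classes `sweep_result`/`data.frame`: one row per
#'   configuration with `length_cm`, `ied_mm`, `area_cm2`,
#'   `n_electrodes`, `pct_identifiable`, `mean_depth_mm`, `sd_depth_mm`,
#'   `seed`.
#' @export
sweep_configs <- function(pool, configs = default_sweep_configs(),
                          fs = 2048, window_ms = 30,
                          tissue = tissue_electrical(),
                          fiber_subsample = 100,
                          config = discriminability_config(),
                          dz = 1, seed = 1) {
  stopifnot(inherits(pool, "mu_pool"))
  if (nrow(configs) == 0L) stop("empty configuration list")
  if (is.null(configs$width_cm)) configs$width_cm <- 3.6
  grids <- lapply(seq_len(nrow(configs)), function(k)
    simulated_grid(configs$length_cm[k], configs$ied_mm[k],
                   configs$width_cm[k]))
  pos_list <- lapply(grids, function(g)
    as.matrix(electrode_positions(g)[, c("x", "y")]))
  all_pos <- do.call(rbind, pos_list)
  key <- paste(round(all_pos[, 1], 6), round(all_pos[, 2], 6))
  master <- all_pos[!duplicated(key), , drop = FALSE]
  mkey <- key[!duplicated(key)]
  wav <- muap_engine(pool, master, fs = fs, window_ms = window_ms,
                     tissue = tissue, fiber_subsample = fiber_subsample,
                     dz = dz, seed = seed)
  res <- vector("list", nrow(configs))
  for (k in seq_len(nrow(configs))) {
    pk <- paste(round(pos_list[[k]][, 1], 6), round(pos_list[[k]][, 2], 6))
    idx <- match(pk, mkey)
    ident <- identifiable_from_array(wav[, idx, , drop = FALSE], fs, config)
    dep <- pool$units$depth[ident]
    res[[k]] <- data.frame(
      length_cm = configs$length_cm[k], ied_mm = configs$ied_mm[k],
      area_cm2 = grid_area(grids[[k]]), n_electrodes = grids[[k]]$n,
      pct_identifiable = 100 * mean(ident),
      mean_depth_mm = if (length(dep)) mean(dep) else NA_real_,
      sd_depth_mm = if (length(dep) > 1) sd(dep) else NA_real_,
      seed = seed)
  }
  structure(do.call(rbind, res), class = c("sweep_result", "data.frame"))
}

#' @export
plot.sweep_result <- function(x, value = "pct_identifiable", ...) {
  ieds <- sort(unique(x$ied_mm))
  areas <- sort(unique(x$area_cm2))
  z <- matrix(NA_real_, length(ieds), length(areas))
  for (k in seq_len(nrow(x))) {
    z[match(x$ied_mm[k], ieds), match(x$area_cm2[k], areas)] <- x[[value]][k]
  }
  image(seq_along(ieds), seq_along(areas), z, axes = FALSE,
        xlab = "IED (mm)", ylab = "grid area (cm^2)",
        col = hcl.colors(64, "viridis"), main = value, ...)
  axis(1, seq_along(ieds), ieds)
  axis(2, seq_along(areas), round(areas, 1))
  invisible(x)
}
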