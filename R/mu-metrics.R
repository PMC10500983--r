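#' Classify motor units as early or late recruited
#'
#' The active pool at a contraction target is the portion of the [fth]
#' law up to the target; its first half (in normalized rank) is "early
#' recruited", the second half "late recruited". A unit with measured
#' recruitment threshold `thr` is early when
#' `thr <= fth(invert_fth(target) / 2)`.
#'
#' @param thresholds Measured recruitment thresholds, % MVC (all
#'   `<= target`).
#' @param target Contraction target, % MVC.
#' @return Character vector of `"early"` / `"late"` labels.
#' @examples
#' classify_early_late(c(0, 11, 12, 29), 30)
#' @export
classify_early_late <- function(thresholds, target) {
  if (any(thresholds > target + 1e-9))
    stop("thresholds must not exceed the contraction target")
  boundary <- fth(invert_fth(min(target, fth(1))) / 2)
  ifelse(thresholds <= boundary, "early", "late")
}

#' Percentage of early-recruited units per condition
#'
#' Per-subject percentages of early-recruited units are averaged across
#' subjects for each condition. A condition is suppressed (reported `NA`
#' with `suppressed = TRUE`) when `min_units` or fewer units were
#' identified in it for at least `min_subjects` subjects.
#'
#' @param labels Data.frame with columns `subject`, `condition`, `early`
#'   (logical or `"early"`/`"late"`), one row per identified unit.
#' @param min_units Suppression unit count (default 5).
#' @param min_subjects Suppression subject count (default 3).
#' @return Data.frame per condition: `condition`, `pct_early`,
#'   `suppressed`.
#' @export
percent_early <- function(labels, min_units = 5, min_subjects = 3) {
  stopifnot(all(c("subject", "condition", "early") %in% names(labels)))
  early <- if (is.logical(labels$early)) labels$early
           else labels$early == "early"
  conds <- unique(labels$condition)
  out <- lapply(conds, function(cc) {
    sub <- labels$condition == cc
    per_subj <- tapply(early[sub], labels$subject[sub], mean) * 100
    counts <- tapply(early[sub], labels$subject[sub], length)
    supp <- sum(counts <= min_units) >= min_subjects
    data.frame(condition = cc,
               pct_early = if (supp) NA_real_ else mean(per_subj),
               suppressed = supp)
  })
  do.call(rbind, out)
}

#' Spike-triggered average of multichannel EMG
#'
#' Estimates a unit's multichannel MUAP by averaging EMG segments
#' centered on its discharge times over a window (default 50 ms).
#' Segments extending past the signal edges are dropped.
#'
#' @param emg Numeric matrix `channels x samples` or a [synthetic_emg].
#' @param spike_times Discharge times, s.
#' @param fs Sampling rate, Hz (taken from the object if given).
#' @param window_ms Averaging window, ms (default 50).
#' @return Numeric matrix `channels x window samples`.
#' @export
sta_muap <- function(emg, spike_times, fs = NULL, window_ms = 50) {
  if (inherits(emg, "synthetic_emg")) { fs <- emg$fs; emg <- emg$data }
  stopifnot(is.matrix(emg), !is.null(fs))
  nw <- as.integer(round(window_ms * fs / 1000))
  half <- nw %/% 2L
  centers <- round(spike_times * fs) + 1L
  ok <- centers - half >= 1L & centers - half + nw - 1L <= ncol(emg)
  if (!any(ok)) stop("no usable discharges inside the signal bounds")
  centers <- centers[ok]
  acc <- matrix(0, nrow(emg), nw)
  for (cix in centers)
    acc <- acc + emg[, (cix - half):(cix - half + nw - 1L), drop = FALSE]
  acc / length(centers)
}

#' Mean correlation between adjacent-electrode MUAP waveforms
#'
#' Locates the electrode with the highest MUAP peak-to-peak amplitude,
#' then averages the Pearson correlation between its waveform and the
#' waveforms of the (up to four) electrodes at distance `d_mm` along the
#' two lattice axes.
#'
#' @param muap Numeric matrix `channels x samples` in the grid's
#'   electrode order.
#' @param grid A [grid_spec].
#' @param d_mm Neighbor distance, mm (a multiple of the grid IED).
#' @return Mean correlation over the available neighbors.
#' @export
adjacent_correlation <- function(muap, grid, d_mm) {
  stopifnot(is.matrix(muap), inherits(grid, "grid_spec"),
            nrow(muap) == grid$n)
  step <- d_mm / grid$ied
  if (abs(step - round(step)) > 1e-9)
    stop("'d_mm' must be a multiple of the grid IED")
  step <- as.integer(round(step))
  pos <- electrode_positions(grid)
  p2p <- apply(muap, 1, function(x) diff(range(x)))
  best <- which.max(p2p)
  r0 <- pos$row[best]; c0 <- pos$col[best]
  nb <- rbind(c(r0 + step, c0), c(r0 - step, c0),
              c(r0, c0 + step), c(r0, c0 - step))
  idx <- match(paste(nb[, 1], nb[, 2]), paste(pos$row, pos$col))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no neighbor electrode at the requested distance")
  mean(vapply(idx, function(k) cor(muap[best, ], muap[k, ]), numeric(1)))
}

#' Normalize motor-unit counts within subjects
#'
#' Expresses each subject's per-condition count as a percentage of that
#' subject's maximum across conditions.
#'
#' @param table Data.frame with columns `subject`, `condition`, `N`.
#' @return The input with an added column `N_norm` in `[0, 100]` (class
#'   `count_table`).
#' @export
normalize_counts <- function(table) {
  stopifnot(all(c("subject", "condition", "N") %in% names(table)))
  mx <- tapply(table$N, table$subject, max)
  if (any(mx <= 0)) stop("a subject has no identified units in any condition")
  table$N_norm <- 100 * table$N / as.numeric(mx[as.character(table$subject)])
  class(table) <- c("count_table", "data.frame")
  table
}

#' Weighted logarithmic trend fit
#'
#' Weighted least-squares fit of `y = a + b * ln(x)`, the natural-log
#' trend relating normalized unit counts to interelectrode distance,
#' grid size, or electrode number. Conditions sharing an electrode count
#' can be down-weighted (weight 0.5) through `weights`.
#'
#' @param x Positive predictor values.
#' @param y Response values.
#' @param weights Per-point weights (default all 1).
#' @return An object of class `trend_fit`: `a` (intercept), `b` (slope
#'   per natural-log unit), `r2` (weighted), `p` (slope t-test),
#'   `weights`, `fit` (the underlying `lm`).
#' @export
fit_log_trend <- function(x, y, weights = NULL) {
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x <= 0)) stop("'x' must be positive")
  if (is.null(weights)) weights <- rep(1, length(x))
  df <- data.frame(x = x, y = y, w = weights)
  fit <- lm(y ~ log(x), data = df, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a benign warning
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]),
                 weights = weights, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Log trend: y = %.3g %+.3g ln(x)  (r2 = %.3f, p = %.3g)\n",
              x$a, x$b, x$r2, x$p))
  invisible(x)
}

#' @export
predict.trend_fit <- function(object, newdata, ...) {
  object$a + object$b * log(newdata)
}

#' Rate of agreement between a found and a reference spike train
#'
#' Greedily matches discharges one-to-one within `tol_s` after aligning
#' the two trains at the lag (bounded by `max_lag_s`) that maximizes the
#' number of matches.
#' `RoA = common / (common + only_found + only_truth)`.
#'
#' @param found,truth Discharge-time vectors, s.
#' @param tol_s Matching tolerance, s (default 5e-4).
#' @param max_lag_s Maximum alignment lag, s (default 0.01).
#' @return A fraction in `[0, 1]`.
#' @examples
#' rate_of_agreement(1:90 / 10, 1:100 / 10)  # 0.9
#' @export
rate_of_agreement <- function(found, truth, tol_s = 5e-4, max_lag_s = 0.01) {
  if (!length(found) && !length(truth)) return(1)
  if (!length(found) || !length(truth)) return(0)
  found <- sort(found); truth <- sort(truth)
  bc <- best_common(found, truth, tol_s, max_lag_s)
  cm <- bc$common
  cm / (cm + (length(found) - cm) + (length(truth) - cm))
}

#' Match decomposed trains against ground-truth spike trains
#'
#' Convenience wrapper: for every accepted train of a
#' [decompose] result, finds the ground-truth unit with the highest
#' [rate_of_agreement].
#'
#' @param result A `decomposition_result`.
#' @param trains A [simulate_discharges] result (the ground truth).
#' @param tol_s,max_lag_s Forwarded to [rate_of_agreement].
#' @return Data.frame: `found_unit`, `truth_unit`, `roa`, `pnr_db`.
#' @export
match_ground_truth <- function(result, trains, tol_s = 5e-4,
                               max_lag_s = 0.01) {
  out <- lapply(seq_along(result$trains), function(k) {
    ft <- result$trains[[k]]$times
    roas <- vapply(trains$times, function(tt)
      rate_of_agreement(ft, tt, tol_s, max_lag_s), numeric(1))
    best <- which.max(roas)
    data.frame(found_unit = k, truth_unit = best, roa = roas[best],
               pnr_db = result$trains[[k]]$pnr)
  })
  do.call(rbind, out)
}
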