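# small shared fixture: clean two-unit mixture with disjoint waveforms
make_toy_mix <- function(fs = 2048, dur = 12, seed = 1) {
  set.seed(seed)
  nt <- round(dur * fs)
  nch <- 10
  # two distinct multichannel MUAPs, 12 ms long
  L <- round(0.012 * fs)
  w1 <- outer(exp(-((1:nch) - 3)^2 / 4), diff(dnorm(seq(-3, 3, length.out = L + 1))))
  w2 <- outer(exp(-((1:nch) - 8)^2 / 4),
              diff(dnorm(seq(-3, 3, length.out = L + 1)) * sin(seq(0, 6, length.out = L + 1))))
  t1 <- seq(0.5, dur - 0.5, by = 0.11) + runif(length(seq(0.5, dur - 0.5, by = 0.11)), 0, 0.02)
  t2 <- seq(0.52, dur - 0.5, by = 0.13) + runif(length(seq(0.52, dur - 0.5, by = 0.13)), 0, 0.02)
  emg <- matrix(0, nch, nt)
  add <- function(emg, w, tt) {
    for (t0 in round(tt * fs)) {
      cols <- t0 + seq_len(ncol(w))
      emg[, cols] <- emg[, cols] + w
    }
    emg
  }
  emg <- add(emg, w1 * 60, t1)
  emg <- add(emg, w2 * 45, t2)
  list(emg = emg, fs = fs, t1 = sort(t1), t2 = sort(t2))
}

test_that("preprocessing is zero-phase band-pass with outlier channel rejection", {
  fs <- 2048
  tt <- seq(0, 2, by = 1 / fs)
  base <- matrix(rnorm(10 * length(tt)), 10)
  cfg <- decomp_config()
  # out-of-band tone attenuated > 20 dB, passband tone preserved
  tone <- function(f) sin(2 * pi * f * tt)
  x <- base
  x[1, ] <- x[1, ] + 50 * tone(1000)
  x[2, ] <- x[2, ] + 50 * tone(100)
  pp <- preprocess_emg(x, fs = fs, config = cfg)
  g1000 <- sd(pp$data[1, ] - mean(pp$data[1, ])) / sd(50 * tone(1000))
  expect_lt(20 * log10(g1000), -20)
  amp100 <- sqrt(2) * sd(signal::filtfilt(signal::butter(2, c(20, 500) / (fs / 2), "pass"),
                                          50 * tone(100)))
  expect_equal(amp100 / 50, 1, tolerance = 0.05)
  # one huge-amplitude noise channel among clean ones is rejected
  y <- base
  y[4, ] <- 400 * rnorm(length(tt))
  pp2 <- preprocess_emg(y, fs = fs, config = cfg)
  expect_false(pp2$keep[4])
  expect_true(all(pp2$keep[-4]))
  expect_error(preprocess_emg(base[1:4, ], fs = 800), "1000")
})

test_that("extension reaches the target and whitening is exact", {
  set.seed(3)
  x <- matrix(rnorm(64 * 4000), 64)
  ew <- extend_and_whiten(x, 1000)
  expect_equal(ew$R, 16L)
  expect_equal(ew$n_extended, 1024L)
  ew256 <- extend_and_whiten(matrix(rnorm(256 * 3000), 256), 1000)
  expect_equal(ew256$R, 4L)
  expect_equal(ew256$n_extended, 1024L)
  # covariance of the whitened output is the identity on the subspace
  C <- tcrossprod(ew$Z) / ncol(ew$Z)
  expect_lt(max(abs(C - diag(nrow(C)))), 1e-6)
})

test_that("a clean two-source mixture is recovered with near-perfect agreement", {
  toy <- make_toy_mix()
  ew <- extend_and_whiten(toy$emg, 1000)
  cfg <- decomp_config(min_peak_dist_s = 0.02)
  tr1 <- extract_source(ew$Z, toy$fs, config = cfg)
  # extension by R = 100 delays can offset the source by up to ~60 ms
  roa <- function(tt) max(rate_of_agreement(tt, toy$t1, max_lag_s = 0.08),
                          rate_of_agreement(tt, toy$t2, max_lag_s = 0.08))
  expect_true(tr1$converged)
  expect_gt(roa(tr1$times), 0.99)
  # deflation: the next source is orthogonal and is the other unit
  tr2 <- extract_source(ew$Z, toy$fs, prior = cbind(tr1$w), config = cfg)
  expect_lt(abs(sum(tr1$w * tr2$w)), 1e-6)
})

test_that("spike classification separates bimodal peak amplitudes exactly", {
  fs <- 2048
  s <- rep(0.01, 3000)
  hi <- seq(100, 2900, by = 100)
  lo <- seq(150, 2900, by = 100)
  s[hi] <- 1; s[lo] <- 0.1
  sp <- emgrid:::detect_spikes(s, fs, min_peak_dist_s = 0.01)
  expect_setequal(sp, hi)
})

test_that("PNR matches its closed form and the gate logic", {
  fs <- 2048
  s <- rep(0, 2048)
  spikes <- seq(64, 2048, by = 64)
  s[spikes] <- 1
  s[-spikes] <- rnorm(2048 - length(spikes), sd = 0.1)
  p <- pnr(s, (spikes - 1) / fs, fs)
  expect_equal(p, 10 * log10(1 / 0.01), tolerance = 0.5)
  # saturated baseline
  s0 <- rep(0, 1000); s0[c(100, 300)] <- 1
  expect_equal(pnr(s0, c(99, 299) / fs, fs), Inf)
  expect_error(pnr(s0, numeric(0), fs), "discharge")
})

test_that("CoV-ISI refinement recovers deleted discharges", {
  toy <- make_toy_mix(seed = 5)
  ew <- extend_and_whiten(toy$emg, 1000)
  cfg <- decomp_config(min_peak_dist_s = 0.02)
  tr <- extract_source(ew$Z, toy$fs, config = cfg)
  truth <- if (rate_of_agreement(tr$times, toy$t1, max_lag_s = 0.08) >
               rate_of_agreement(tr$times, toy$t2, max_lag_s = 0.08))
    toy$t1 else toy$t2
  expect_gt(rate_of_agreement(tr$times, truth, max_lag_s = 0.08), 0.99)
  # delete 10% of its spikes and refine
  del <- tr
  keep <- seq_along(tr$spikes) %% 10 != 0
  del$spikes <- tr$spikes[keep]
  del$times <- tr$times[keep]
  del$cov_isi <- emgrid:::cov_isi(del$times)
  ref <- refine_by_cov(del, ew$Z, toy$fs, cfg)
  n_deleted <- sum(!keep)
  recovered <- length(ref$times) - length(del$times)
  expect_gte(recovered, ceiling(n_deleted / 2))
  expect_lte(ref$cov_isi, del$cov_isi)
  # accepted CoV sequence is nonincreasing
  expect_true(all(diff(ref$cov_history) <= 0))
  # a fixed point returns unchanged
  again <- refine_by_cov(ref, ew$Z, toy$fs, cfg)
  expect_equal(again$times, ref$times)
  # too few spikes: unchanged with flag
  few <- tr; few$spikes <- tr$spikes[1:3]; few$times <- tr$times[1:3]
  expect_false(refine_by_cov(few, ew$Z, toy$fs, cfg)$refined)
})

test_that("duplicate removal applies the common-discharge rule", {
  mk <- function(times, cv) structure(list(times = times, cov_isi = cv),
                                      class = "pulse_train")
  base <- sort(runif(100, 0, 30))
  # identical trains: one survivor (the lower CoV one)
  out <- remove_duplicates(list(mk(base, 0.2), mk(base, 0.1)))
  expect_length(out$trains, 1)
  expect_equal(out$trains[[1]]$cov_isi, 0.1)
  # a 3-ms-delayed exact copy is found via alignment
  out2 <- remove_duplicates(list(mk(base, 0.2), mk(base + 0.003, 0.3)))
  expect_length(out2$trains, 1)
  expect_equal(out2$removed, 1L)
  # 29% shared discharges: both kept
  a <- (1:100) * 0.3
  b <- c(a[1:29], a[30:100] + 0.09)   # 29 common, rest offset beyond window
  out3 <- remove_duplicates(list(mk(a, 0.2), mk(b, 0.3)))
  expect_length(out3$trains, 2)
  # 30% shared: duplicates
  b2 <- c(a[1:30], a[31:100] + 0.09)
  out4 <- remove_duplicates(list(mk(a, 0.2), mk(b2, 0.3)))
  expect_length(out4$trains, 1)
})

test_that("decomposition is deterministic and its dedup audit holds", {
  toy <- make_toy_mix(seed = 9)
  cfg <- decomp_config(n_runs = 6, min_peak_dist_s = 0.02, seed = 3)
  r1 <- decompose(toy$emg, config = cfg, fs = toy$fs)
  r2 <- decompose(toy$emg, config = cfg, fs = toy$fs)
  expect_equal(summary(r1), summary(r2))
  expect_gte(length(r1$trains), 1)
  # post-hoc audit: no accepted pair violates the duplicate rule
  # (alignment search covers the R = 100 extension offsets)
  if (length(r1$trains) > 1) {
    for (i in seq_along(r1$trains)[-1]) for (j in seq_len(i - 1)) {
      lag_eff <- cfg$dedup_max_lag_s + ceiling(1000 / 10) / toy$fs
      bc <- emgrid:::best_common(r1$trains[[i]]$times, r1$trains[[j]]$times,
                                 5e-4, max_lag_s = lag_eff)
      share <- bc$common / min(length(r1$trains[[i]]$times),
                               length(r1$trains[[j]]$times))
      expect_lt(share, 0.30)
    }
  }
  # all accepted trains are real sources
  for (tr in r1$trains) {
    roa <- max(rate_of_agreement(tr$times, toy$t1, max_lag_s = 0.15),
               rate_of_agreement(tr$times, toy$t2, max_lag_s = 0.15),
               rate_of_agreement(tr$times, toy$t1, max_lag_s = 0.15,
                                 tol_s = 5e-4),
               rate_of_agreement(tr$times, toy$t2, max_lag_s = 0.15,
                                 tol_s = 5e-4))
    expect_gt(roa, 0.95)
  }
})
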