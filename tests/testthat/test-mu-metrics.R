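test_that("early/late classification splits the active pool at its rank midpoint", {
  expect_equal(classify_early_late(0, 30), "early")
  # boundary for a 30% MVC target: fth(invert_fth(30)/2) ~ 11.5 %MVC
  boundary <- fth(invert_fth(30) / 2)
  expect_equal(boundary, 11.5, tolerance = 0.05)
  expect_equal(classify_early_late(c(11, 12), 30), c("early", "late"))
  expect_true(all(classify_early_late(c(15, 20, 29), 30) == "late"))
  expect_error(classify_early_late(35, 30), "target")
})

test_that("early-recruited percentages are suppressed by the sparse-data rule", {
  lab <- expand.grid(subject = 1:6, unit = 1:10)
  lab$condition <- "dense"
  lab$early <- lab$unit <= 3   # 30% early for every subject
  out <- percent_early(lab)
  expect_equal(out$pct_early, 30)
  expect_false(out$suppressed)
  # three subjects with five units each: suppressed
  sparse <- expand.grid(subject = 1:3, unit = 1:5)
  sparse$condition <- "sparse"
  sparse$early <- TRUE
  out2 <- percent_early(rbind(lab, sparse))
  expect_true(out2$suppressed[out2$condition == "sparse"])
  expect_true(is.na(out2$pct_early[out2$condition == "sparse"]))
  expect_false(out2$suppressed[out2$condition == "dense"])
})

test_that("ground-truth early labels are recovered from noiseless thresholds", {
  prof <- trapezoid_profile(30, 20)
  tr <- simulate_discharges(prof, 200, seed = 3)
  active <- lengths(tr$times) > 0
  lab <- classify_early_late(tr$threshold[active], 30)
  expect_gte(mean((lab == "early") == tr$early[active]), 0.99)
})

test_that("spike-triggered averaging recovers the true MUAP", {
  pool <- build_pool(count = 4, seed = 8)
  grid <- grid_spec(6, 4, ied = 8)
  muaps <- compute_muaps(pool, grid, fiber_subsample = 80, seed = 8,
                         window_ms = 50)
  prof <- trapezoid_profile(30, 20)
  tr <- simulate_discharges(prof, 4, seed = 8)
  # noise-free single spike: STA returns the exact segment
  solo <- tr
  solo$times <- list(numeric(0), c(2), numeric(0), numeric(0))
  clean <- render_emg(muaps, solo, snr_db = Inf)
  sta1 <- sta_muap(clean$data, 2 + 0.025, fs = clean$fs, window_ms = 50)
  nt <- ncol(sta1)
  expect_equal(dim(sta1), c(grid$n, nt))
  # averaging N identical segments equals one segment
  rep3 <- sta_muap(clean$data, rep(2 + 0.025, 3), fs = clean$fs,
                   window_ms = 50)
  expect_equal(rep3, sta1)
  # noisy many-spike recovery: channel-wise correlation > 0.95
  emg <- render_emg(muaps, tr, snr_db = 20, seed = 8)
  u <- 2
  expect_gte(length(tr$times[[u]]), 200)
  sta <- sta_muap(emg$data, tr$times[[u]] + 0.025, fs = emg$fs,
                  window_ms = 50)
  true_w <- muaps$waveforms[u, , ]
  cc <- vapply(seq_len(grid$n), function(ch)
    cor(sta[ch, seq_len(min(ncol(sta), ncol(true_w)))],
        true_w[ch, seq_len(min(ncol(sta), ncol(true_w)))]), numeric(1))
  expect_gt(mean(cc), 0.95)
  expect_error(sta_muap(clean$data, 1e6, fs = clean$fs), "usable")
})

test_that("adjacent-electrode correlation behaves at the limits", {
  g <- grid_spec(5, 5, ied = 4)
  # identical channels: rho = 1
  w <- matrix(rep(sin(1:50), g$n), g$n, byrow = TRUE)
  w[13, ] <- 2 * w[13, ]   # center electrode has the largest amplitude
  expect_equal(adjacent_correlation(w, g, 4), 1)
  # independent noise: |rho| near 0
  set.seed(4)
  wn <- matrix(rnorm(g$n * 1e4), g$n)
  wn[13, ] <- wn[13, ] * 3
  expect_lt(abs(adjacent_correlation(wn, g, 4)), 0.1)
  expect_error(adjacent_correlation(w, g, 3), "multiple")
  w2 <- matrix(rnorm(2 * 30), 2)
  expect_error(adjacent_correlation(w2, grid_spec(1, 2, 4), 8), "neighbor")
})

test_that("adjacent-MUAP correlation decreases with electrode distance", {
  pool <- build_pool(count = 20, seed = 2)
  grid <- composite_grid()
  muaps <- compute_muaps(pool, grid, fiber_subsample = 60, seed = 2)
  rho <- vapply(c(4, 8, 12, 16), function(d) {
    mean(vapply(1:20, function(u)
      adjacent_correlation(muaps$waveforms[u, , ], grid, d), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rho) < 0))
})

test_that("count normalization is a within-subject percentage", {
  tab <- data.frame(subject = c(1, 1, 2, 2), condition = c("a", "b", "a", "b"),
                    N = c(10, 5, 40, 50))
  out <- normalize_counts(tab)
  expect_equal(out$N_norm, c(100, 50, 80, 100))
  # permutation invariance
  out2 <- normalize_counts(tab[c(4, 1, 3, 2), ])
  expect_equal(sort(out2$N_norm), sort(out$N_norm))
  expect_error(normalize_counts(data.frame(subject = 1, condition = "a",
                                           N = 0)), "no identified")
})

test_that("weighted log trend fit matches the normal-equations oracle", {
  x <- c(2, 4, 8, 12, 16, 24)
  # exact fit recovered to 1e-9
  y <- 195 - 68 * log(x)
  f <- fit_log_trend(x, y)
  expect_equal(f$a, 195, tolerance = 1e-9)
  expect_equal(f$b, -68, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # natural-log convention: the printed-style coefficients give ~100 at
  # the 4-mm normalization anchor (base-10 would give ~153)
  expect_equal(195 - 68 * log(4), 100, tolerance = 6)
  expect_false(abs(195 - 68 * log10(4) - 100) < 6)
  # weighted fit equals closed-form weighted least squares
  set.seed(5)
  y2 <- y + rnorm(6, sd = 8)
  w <- c(1, 0.5, 1, 0.5, 1, 1)
  fw <- fit_log_trend(x, y2, weights = w)
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y2))
  expect_equal(c(fw$a, fw$b), as.numeric(beta), tolerance = 1e-9)
  # weights change the fit on an asymmetric fixture
  f0 <- fit_log_trend(x, y2)
  expect_false(isTRUE(all.equal(f0$b, fw$b)))
  expect_error(fit_log_trend(x[1:2], y2[1:2]), "3 points")
})

test_that("rate of agreement counts matched and unmatched discharges", {
  tt <- sort(runif(100, 0, 30))
  expect_equal(rate_of_agreement(tt, tt), 1)
  expect_equal(rate_of_agreement(tt, tt + 100), 0)
  # truth 100, found = truth minus 10: common 90, only_truth 10
  expect_equal(rate_of_agreement(tt[-(1:10)], tt), 90 / 100)
  expect_equal(rate_of_agreement((1:90) / 10, (1:100) / 10), 90 / 100,
               tolerance = 1e-12)
  # 10 deletions plus 10 insertions: 90 / (90 + 10 + 10)
  expect_equal(rate_of_agreement(c(tt[-(1:10)], 40 + (1:10)), tt), 90 / 110)
  # alignment: a constant 3-ms offset is absorbed
  expect_equal(rate_of_agreement(tt + 0.003, tt), 1)
})
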