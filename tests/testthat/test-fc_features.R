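test_that("instantaneous phase advances linearly for a pure tone", {
  fs <- 80
  tt <- (seq_len(10 * fs) - 1) / fs
  ph <- instantaneous_phase(cos(2 * pi * 7 * tt))
  interior <- seq(40, length(ph) - 40)
  up <- unwrap_phase(ph)[interior]
  slope <- coef(lm(up ~ tt[interior]))[2]
  expect_equal(as.numeric(slope), 2 * pi * 7, tolerance = 0.01 * 2 * pi * 7)
})

test_that("phase has the quadrature identity and amplitude invariance", {
  fs <- 80
  tt <- (seq_len(5 * fs) - 1) / fs
  ps <- instantaneous_phase(sin(2 * pi * 8 * tt))
  pc <- instantaneous_phase(cos(2 * pi * 8 * tt))
  interior <- seq(20, length(ps) - 20)
  d <- (pc - ps)[interior]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 2)), 0.05)

  x <- sin(2 * pi * 8 * tt) + 0.1 * cos(2 * pi * 9 * tt)
  expect_equal(instantaneous_phase(x), instantaneous_phase(2 * x),
               tolerance = 1e-10)
  expect_error(instantaneous_phase(rep(0, 100)), class = "lcasonify_param_error")
})

test_that("PLV is 1 for identical or constant-lag signals and symmetric", {
  fs <- 80
  tt <- (seq_len(10 * fs) - 1) / fs
  x <- sin(2 * pi * 10 * tt)
  expect_equal(plv(x, x), 1, tolerance = 1e-9)
  expect_equal(plv(sin(2 * pi * 10 * tt), cos(2 * pi * 10 * tt)), 1,
               tolerance = 1e-3)
  y <- sin(2 * pi * 10 * tt + 0.7)
  expect_equal(plv(x, y), plv(y, x), tolerance = 1e-12)
  expect_equal(plv(3 * x, y), plv(x, y), tolerance = 1e-9)
  expect_error(plv(x, y[-1]), class = "lcasonify_param_error")
})

test_that("PLV of independent uniform phases matches the Rayleigh statistic", {
  n <- 960
  sims <- withr::with_seed(99, sapply(seq_len(1000), function(i) {
    lcasonify:::plv_from_phase_diff(runif(n, 0, 2 * pi))
  }))
  expect_equal(mean(sims), sqrt(pi) / 2 / sqrt(n), tolerance = 0.05)
})

test_that("GFC follows the Gaussian-kernel identities", {
  x <- rnorm(64)
  expect_identical(gfc(x, x, 2), 1)
  expect_equal(gfc(c(1, 0), c(0, 1), 1), exp(-1), tolerance = 1e-12)
  # ||d||^2 = 2 sigma^2 gives e^-1 for any sigma
  s <- 1.7
  y <- x + sqrt(2) * s / sqrt(64) * rep(1, 64) *
    sign(rnorm(1))  # ||x - y||^2 = 2 s^2
  expect_equal(gfc(x, y, s), exp(-1), tolerance = 1e-9)
  expect_error(gfc(x, x, 0), class = "lcasonify_param_error")
  # amplitude sensitivity (in contrast to PLV)
  expect_false(isTRUE(all.equal(gfc(x, 2 * x, 1), gfc(x, x, 1))))
})

test_that("bandwidth selection maximizes the spread of kernel values", {
  # two-cluster pairwise distances {d, 10d}: rows at 0, d and 10d
  d <- 2
  W <- rbind(rep(0, 16), rep(d / 4, 16), rep(10 * d / 4, 16))
  grid <- exp(seq(log(0.05), log(50), length.out = 400))
  sel <- select_bandwidth(W, grid = grid, scale = FALSE)
  dists <- as.vector(dist(W))
  oracle <- grid[which.max(sapply(grid, function(s) var(exp(-dists^2 / (2 * s^2)))))]
  expect_equal(as.numeric(sel), oracle)
  # the maximizer is interior: tiny and huge sigmas give lower variance
  vars <- attr(sel, "variance")
  expect_gt(max(vars), vars[1])
  expect_gt(max(vars), vars[length(vars)])

  # degenerate single pair: grid median with a warning
  single <- rbind(rep(0, 8), rep(1, 8))
  expect_warning(out <- select_bandwidth(single, grid = c(1, 2, 3), scale = FALSE),
                 "Degenerate")
  expect_equal(as.numeric(out), 2)
  expect_error(select_bandwidth(W, grid = numeric(0)), class = "lcasonify_param_error")
})

test_that("connectivity matrices are symmetric, unit-diagonal and in [0, 1]", {
  spec <- coupled_eeg_spec(seed = 5, n_trials = 2)
  eeg <- gen_eeg_trials(spec)
  w <- eeg$data[1, , ]
  for (ms in c("plv", "gfc")) {
    M <- connectivity_matrix(w, ms, sigma = 5)
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
  expect_error(connectivity_matrix(w, "gfc"), class = "lcasonify_param_error")
  expect_error(connectivity_matrix(w[1, , drop = FALSE], "plv"),
               class = "lcasonify_param_error")
})

test_that("identical channels give an all-ones matrix; a planted pair is the off-diagonal max", {
  x <- sin(2 * pi * 6 * (1:128) / 64)
  w3 <- rbind(x, x, x)
  expect_equal(max(abs(connectivity_matrix(w3, "plv") - 1)), 0, tolerance = 1e-9)

  spec <- coupled_eeg_spec(seed = 8, n_trials = 4, noise_sd = 0.3)
  eeg <- gen_eeg_trials(spec)
  tr <- which(eeg$labels == "HAPV")[1]   # amp 1.5 coupling on (F3, F4)
  w <- eeg$data[tr, , ]
  for (ms in c("plv", "gfc")) {
    M <- connectivity_matrix(w, ms, sigma = if (ms == "gfc")
      as.numeric(select_bandwidth(w)) else NULL)
    off <- M - diag(diag(M))
    idx <- which(off == max(off), arr.ind = TRUE)
    expect_equal(sort(idx[1, ]), c(1, 2), ignore_attr = TRUE)
  }
})

test_that("feature extraction obeys the dimension and ordering contracts", {
  # Nphi = 17 -> vectorization length 136
  expect_equal(length(lcasonify:::vectorize_upper(diag(17))), 136L)

  spec <- coupling_spec(n_channels = 14, fs_eeg = 32, trial_length = 12,
                        n_trials_per_subject = 3, noise_sd = 1, seed = 2)
  eeg <- gen_eeg_trials(spec)
  fx <- extract_fc_features(eeg, window_grid(3, 12), bands = "broadband",
                            measures = c("plv", "gfc"))
  expect_equal(ncol(fx$values), 91 * 7 * 1 * 2)  # NFC x Mtau x bands x measures
  expect_equal(nrow(fx$index), ncol(fx$values))
  fx1 <- extract_fc_features(eeg, window_grid(3, 12), bands = "broadband",
                             measures = "plv")
  expect_equal(ncol(fx1$values), 91 * 7)

  # deterministic ordering: (measure, band, window, pair)
  expect_identical(unique(fx$index$measure), c("plv", "gfc"))
  expect_equal(fx$index$window[1:91], rep(1L, 91))

  expect_error(extract_fc_features(eeg, window_grid(3, 12), measures = character(0)),
               class = "lcasonify_param_error")
})

test_that("permuting trials permutes feature rows identically", {
  spec <- coupled_eeg_spec(seed = 4, n_trials = 4)
  eeg <- gen_eeg_trials(spec)
  perm <- c(3, 1, 4, 2)
  eegp <- eeg
  eegp$data <- eeg$data[perm, , , drop = FALSE]
  eegp$labels <- eeg$labels[perm]
  f1 <- extract_fc_features(eeg, window_grid(3, 3), bands = "broadband",
                            sigma = 4)
  f2 <- extract_fc_features(eegp, window_grid(3, 3), bands = "broadband",
                            sigma = 4)
  expect_equal(f2$values, f1$values[perm, ], tolerance = 1e-12)
})

test_that("label-dependent coupling separates planted from unplanted pairs", {
  # between-label mean FC difference for the planted pair exceeds the
  # largest unplanted-pair difference in most seeds
  hits <- sum(sapply(seq_len(12), function(s) {
    eeg <- gen_eeg_trials(coupled_eeg_spec(seed = s, n_trials = 24))
    fx <- extract_fc_features(eeg, window_grid(3, 3), bands = "broadband",
                              measures = "plv")
    ip <- which(fx$index$ch1 == "F3" & fx$index$ch2 == "F4")
    diffs <- apply(fx$values, 2, function(v) {
      abs(mean(v[eeg$labels == "HAPV"]) - mean(v[eeg$labels == "LAPV"]))
    })
    diffs[ip] == max(diffs)
  }))
  expect_gte(hits, 11)
})
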