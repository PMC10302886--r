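test_that("gamma matches hand computations on separable groups", {
  g <- clustering_gamma(c(0, 0, 10, 10), c("a", "a", "b", "b"))
  expect_equal(g$silhouette_term, 1)
  expect_equal(g$scatter_term, 0)
  expect_equal(g$gamma, g$silhouette_term + g$scatter_term)

  # two tight groups far apart in 2-D
  pts <- rbind(matrix(0, 3, 2), matrix(100, 3, 2))
  g2 <- clustering_gamma(pts, rep(c("a", "b"), each = 3))
  expect_equal(g2$silhouette_term, 1)
  expect_equal(g2$scatter_term, 0)

  expect_error(clustering_gamma(pts, rep("a", 6)), class = "lcasonify_param_error")
})

test_that("shuffled labels collapse the silhouette term to its null", {
  pts <- withr::with_seed(10, rbind(matrix(rnorm(40, 0), 20, 2),
                                    matrix(rnorm(40, 8), 20, 2)))
  labs <- rep(c("a", "b"), each = 20)
  s_obs <- clustering_gamma(pts, labs)$silhouette_term
  null_s <- withr::with_seed(11, sapply(seq_len(500), function(i) {
    clustering_gamma(pts, sample(labs))$silhouette_term
  }))
  s_shuf <- withr::with_seed(12, clustering_gamma(pts, sample(labs))$silhouette_term)
  expect_lt(s_shuf, quantile(null_s, 0.95))
  expect_gt(s_obs, quantile(null_s, 0.95))
  # bounds
  expect_true(s_obs >= -1 && s_obs <= 1)
})

test_that("gamma increases monotonically with cluster separation", {
  seps <- c(0.5, 1, 2, 4, 8)
  base <- withr::with_seed(13, matrix(rnorm(60 * 2, sd = 0.5), 60, 2))
  vals <- sapply(seps, function(s) {
    pts <- base + outer(rep(c(0, s), each = 30), c(1, 1))
    clustering_gamma(pts, rep(c("a", "b"), each = 30))$gamma
  })
  expect_true(all(diff(vals) > 0))
})

test_that("the silhouette variant drops the scatter term", {
  pts <- withr::with_seed(14, matrix(rnorm(40 * 2, sd = 2), 40, 2))
  labs <- rep(c("a", "b"), 20)
  ga <- clustering_gamma(pts, labs)
  gs <- clustering_gamma(pts, labs, variant = "silhouette")
  expect_equal(gs$gamma, gs$silhouette_term)
  expect_equal(ga$gamma, ga$silhouette_term + ga$scatter_term)
  expect_gte(ga$scatter_term, 0)
})

test_that("leave-one-subject-out produces one fold per subject", {
  mk <- function(seed, rho = 0.9) {
    g <- gen_coupled_features(80, 6, 5, rho, label_sep = 1, seed = seed)
    list(X = g$X, Y = g$Y, labels = g$labels)
  }
  subj <- lapply(1:3, mk)
  out <- loso_correlation(subj, d = 3, max_iter = 20)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$r_squared >= 0 & out$r_squared <= 1))
  expect_error(loso_correlation(subj[1]), class = "lcasonify_param_error")

  # identical subjects: fold estimates are exchangeable, variance ~ 0
  same <- list(mk(5), mk(5), mk(5))
  out2 <- loso_correlation(same, d = 3, max_iter = 20)
  expect_lt(sd(out2$r_squared), 1e-8)

  # one decoupled subject is the worst fold
  mixed <- list(mk(1), mk(2), mk(3), mk(99, rho = 0))
  out3 <- loso_correlation(mixed, d = 3, max_iter = 20)
  expect_equal(which.min(out3$r_squared), 4L)
})

test_that("dynamic resolution is the mean absolute neighbour difference", {
  expect_equal(dynamic_resolution(rep(0.4, 6)), 0)
  expect_equal(dynamic_resolution(c(0, 1, 0)), 1)
  r <- withr::with_seed(15, runif(25))
  loop <- 0
  for (m in seq_len(24)) loop <- loop + abs(r[m + 1] - r[m])
  expect_equal(dynamic_resolution(r), loop / 24)
  expect_error(dynamic_resolution(0.2), class = "lcasonify_param_error")
})

test_that("the window sweep covers the full study grid", {
  spec <- coupling_spec(n_channels = 4, fs_eeg = 32, trial_length = 12,
                        n_trials_per_subject = 8, noise_sd = 1, seed = 3)
  eeg <- gen_eeg_trials(spec)
  Y <- withr::with_seed(3, matrix(rnorm(8 * 4), 8, 4))
  sw <- lca_sweep(eeg, Y, axis = "window", d = 2, max_iter = 10, seed = 1)
  expect_equal(nrow(sw), 6L)
  expect_equal(as.numeric(sw$setting), c(12, 6, 3, 1.5, 0.75, 0.375))
  expect_true(all(sw$r_squared_sd >= 0, na.rm = TRUE))
})

test_that("the electrode-set sweep produces one entry per montage", {
  chans <- c("F3", "F4", "Pz", "O1", "O2", "C3")
  spec <- coupling_spec(n_channels = 6, channel_names = chans, fs_eeg = 32,
                        trial_length = 3, n_trials_per_subject = 8,
                        noise_sd = 1, seed = 4)
  eeg <- gen_eeg_trials(spec)
  Y <- withr::with_seed(4, matrix(rnorm(8 * 4), 8, 4))
  sw <- lca_sweep(eeg, Y, axis = "electrode_set", settings = c("E17", "E14"),
                  d = 2, max_iter = 10, seed = 1)
  expect_equal(sw$setting, c("E17", "E14"))
  expect_error(lca_sweep(eeg, Y, axis = "bogus"), "arg")
})

test_that("a coupling planted in the alpha band dominates the band sweep", {
  wins <- sum(sapply(1:5, function(s) {
    amps <- c(HAPV = 1.5, HANV = 1, LANV = 0.5, LAPV = 0.25)
    spec <- coupling_spec(
      n_channels = 6, channel_names = small_montage[1:6], fs_eeg = 64,
      trial_length = 3, n_trials_per_subject = 48,
      coupled_pairs = data.frame(ch1 = "F3", ch2 = "F4",
                                 label = names(amps), amp = unname(amps)),
      coupling_freq = 10, coupling_jitter = 0.8, noise_sd = 1,
      amp_mix = 0, seed = s)
    eeg <- gen_eeg_trials(spec)
    lat <- attr(eeg, "trial_latent")
    a_tot <- log(amps[eeg$labels]) + 0.8 * lat
    Y <- withr::with_seed(s, cbind(a_tot + 0.2 * rnorm(48),
                                   matrix(rnorm(48 * 5), 48)))
    sw <- lca_sweep(eeg, Y, axis = "band",
                    settings = c("theta", "alpha", "beta"),
                    d = 2, max_iter = 40, seed = s)
    which.max(sw$r_squared) == 2
  }))
  expect_gte(wins, 3)
})
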