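test_that("GFP is the population across-channel standard deviation", {
  eeg <- eeg_record(rbind(c(1, 2, 0), c(-1, 2, 0)), 100)
  expect_equal(global_field_power(eeg), c(1, 0, 0))
  # homogeneity: scaling the EEG scales the GFP
  set.seed(1)
  x <- matrix(rnorm(40), 4, 10)
  g1 <- global_field_power(eeg_record(x, 100))
  g3 <- global_field_power(eeg_record(-3 * x, 100))
  expect_equal(g3, 3 * g1, tolerance = 1e-12)
  expect_error(global_field_power(eeg_record(x[1, , drop = FALSE], 100)),
               "2 channels")
})

test_that("GFP peaks are strict interior maxima with plateau handling", {
  expect_identical(gfp_peaks(1:10), integer(0))
  expect_identical(gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(gfp_peaks(c(0, 3, 3, 3, 1, 5, 0)), c(2L, 6L))
  expect_identical(gfp_peaks(c(5, 1, 5)), integer(0))  # endpoints excluded
  # 5 Hz amplitude modulation of a 100 Hz-sampled rectified carrier:
  # |sin| has 2 maxima per cycle
  t <- seq(0, 10, by = 0.01)
  g <- abs(sin(2 * pi * 2.5 * t))
  expect_equal(length(gfp_peaks(g)), 50, tolerance = 1)
})

test_that("modified k-means recovers orthogonal templates exactly from clean EEG", {
  maps <- make_test_templates(16, 4, seed = 2)
  gt <- generate_microstate_eeg(maps, 100, 60, snr = Inf, seed = 3)
  fit <- fit_microstates(gt$eeg, K = 4, n_restarts = 5, seed = 1)
  expect_identical(fit$K, 4L)
  m <- match_microstates(fit, microstate_model(maps))
  expect_equal(m$score, 1, tolerance = 1e-6)
})

test_that("modified k-means recovers templates from noisy EEG", {
  maps <- make_test_templates(16, 4, seed = 4)
  gt <- generate_microstate_eeg(maps, 100, 60, snr = 5, seed = 5)
  fit <- fit_microstates(gt$eeg, K = 4, n_restarts = 20, seed = 2)
  m <- match_microstates(fit, microstate_model(maps))
  expect_gte(m$score, 0.95)
  # determinism given the seed
  fit2 <- fit_microstates(gt$eeg, K = 4, n_restarts = 20, seed = 2)
  expect_identical(fit$maps, fit2$maps)
})

test_that("nearly identical templates are merged and K drops", {
  set.seed(6)
  base <- make_test_templates(16, 3, seed = 7)
  near <- base[, 3] + 0.12 * base[, 1]
  near <- near - mean(near); near <- near / sqrt(sum(near^2))
  stopifnot(abs(cor(near, base[, 3])) > 0.95)
  four <- cbind(base, near)
  four <- sweep(four, 2, sqrt(colSums(four^2)), "/")
  gt <- generate_microstate_eeg(four, 100, 60, snr = Inf, seed = 8)
  fit <- fit_microstates(gt$eeg, K = 4, n_restarts = 10, seed = 3)
  expect_lt(fit$K, 4L)
  rc <- cor(fit$maps)
  expect_true(all(abs(rc[upper.tri(rc)]) < 0.9))
})

test_that("segmentation with zero penalty is the per-sample argmax labelling", {
  maps <- make_test_templates(12, 4, seed = 9)
  gt <- generate_microstate_eeg(maps, 60, 20, snr = 3, seed = 10)
  model <- microstate_model(maps)
  seg0 <- segment_smooth(gt$eeg, model, lambda_penalty = 0)
  x <- sweep(gt$eeg$data, 2, colMeans(gt$eeg$data))
  a <- crossprod(maps, x)
  expect_identical(seg0$labels, as.integer(max.col(t(a^2), "first")))
})

test_that("single-template EEG is labelled as one state throughout", {
  maps <- make_test_templates(10, 2, seed = 11)
  env <- abs(sin(seq(0, 20, length.out = 500))) + 0.2
  data <- maps[, 1] %*% t(env)
  eeg <- eeg_record(data, 100)
  model <- microstate_model(maps)
  seg <- segment_smooth(eeg, model)
  expect_true(all(seg$labels == 1L))
})

test_that("smoothing removes injected one-sample label flips", {
  # truth with regular 150 ms runs, so every 1-sample segment is spurious
  set.seed(31)
  maps <- make_test_templates(16, 4, seed = 12)
  n_run <- 400; run_len <- 15
  states <- integer(n_run); states[1] <- 1L
  for (i in 2:n_run) {
    states[i] <- ((states[i - 1] - 1 + sample(3, 1)) %% 4) + 1L
  }
  labs <- rep(states, each = run_len)
  n <- length(labs)
  env <- abs(sin(seq(0, 200, length.out = n))) + 0.3
  signal <- maps[, labs] * rep(env, each = 16)
  sigma <- sqrt(mean(signal^2)) / 2.5
  data <- signal + matrix(rnorm(16 * n, sd = sigma), 16, n)
  flips <- seq(8, n - 8, by = 37)      # isolated single-sample swaps
  for (t in flips) {
    other <- (labs[t] %% 4) + 1
    data[, t] <- maps[, other] * env[t] + rnorm(16, sd = sigma)
  }
  eeg <- eeg_record(sweep(data, 2, colMeans(data)), 100, "common-average")
  model <- microstate_model(maps)
  seg_raw <- segment_smooth(eeg, model, lambda_penalty = 0)
  seg_sm <- segment_smooth(eeg, model, window_b = 3, lambda_penalty = 5)
  acc_raw <- mean(seg_raw$labels == labs)
  acc_sm <- mean(seg_sm$labels == labs)
  # smoothing repairs most injected flips
  expect_gt(mean(seg_sm$labels[flips] == labs[flips]),
            mean(seg_raw$labels[flips] == labs[flips]))
  expect_gt(acc_sm, acc_raw)
  expect_gte(acc_sm, 0.99)
})

test_that("microstate statistics match run-length enumeration by hand", {
  maps <- make_test_templates(8, 2, seed = 15)
  model <- microstate_model(maps)
  labels <- c(1L, 1L, 2L, 2L, 2L, 1L)
  env <- c(1, 1.2, 0.9, 1.1, 1, 0.8)
  data <- maps[, labels] * rep(env, each = 8)
  eeg <- eeg_record(data, 100, "common-average")
  seg <- microstate_segmentation(labels, global_field_power(eeg), 100)
  st <- microstate_stats(seg, model, eeg)
  expect_equal(st$occupation_ratio, c(0.5, 0.5))
  # runs: state 1 lengths (2, 1) -> 15 ms; state 2 length 3 -> 30 ms
  expect_equal(st$mean_transition_time_ms, c(15, 30))
  expect_equal(st$transition_matrix, matrix(c(0, 1, 1, 0), 2),
               ignore_attr = TRUE)
  expect_equal(st$gev, 1, tolerance = 1e-10)   # noiseless template data
})

test_that("GEV is bounded and occupation ratios always sum to one", {
  maps <- make_test_templates(12, 4, seed = 16)
  model <- microstate_model(maps)
  for (s in 1:5) {
    gt <- generate_microstate_eeg(maps, 80, 10, snr = 1, seed = s)
    seg <- segment_smooth(gt$eeg, model)
    st <- microstate_stats(seg, model, gt$eeg)
    expect_gte(st$gev, 0); expect_lte(st$gev, 1)
    expect_equal(sum(st$occupation_ratio), 1, tolerance = 1e-12)
    rs <- rowSums(st$transition_matrix)
    expect_equal(unname(rs[!is.na(rs)]),
                 rep(1, sum(!is.na(rs))), tolerance = 1e-12)
  }
})

test_that("never-visited states report zero occupation and missing dwell", {
  maps <- make_test_templates(8, 3, seed = 17)
  model <- microstate_model(maps)
  labels <- rep(c(1L, 2L), each = 5)
  data <- maps[, labels]
  eeg <- eeg_record(data, 100, "common-average")
  seg <- microstate_segmentation(labels, global_field_power(eeg), 100)
  st <- microstate_stats(seg, model, eeg)
  expect_equal(st$occupation_ratio[3], 0)
  expect_true(is.na(st$mean_transition_time_ms[3]))
})

test_that("matching agrees with brute-force enumeration, sign flips included", {
  set.seed(18)
  for (case in 1:5) {
    ka <- sample(2:4, 1); kb <- sample(2:4, 1)
    a <- microstate_model(make_test_templates(10, ka, seed = case))
    b <- microstate_model(make_test_templates(10, kb, seed = case + 50))
    m <- match_microstates(a, b)
    oracle <- oracle_match_score(cor(a$maps, b$maps))
    expect_equal(m$score, oracle, tolerance = 1e-12)
    # symmetry
    expect_equal(match_microstates(b, a)$score, m$score, tolerance = 1e-12)
  }

  # self-match is perfect; reversal and sign flips are recovered
  a <- microstate_model(make_test_templates(12, 4, seed = 60))
  expect_equal(match_microstates(a, a)$score, 1, tolerance = 1e-12)
  expect_identical(match_microstates(a, a)$permutation, 1:4)
  rev_flip <- microstate_model(a$maps[, 4:1] %*% diag(c(-1, 1, -1, 1)))
  m <- match_microstates(a, rev_flip)
  expect_equal(m$score, 1, tolerance = 1e-12)
  expect_identical(m$permutation, 4:1)

  # missing states contribute zero to the mean
  b3 <- microstate_model(a$maps[, 1:3])
  m43 <- match_microstates(a, b3)
  expect_equal(m43$score, oracle_match_score(cor(a$maps, b3$maps)),
               tolerance = 1e-12)
  expect_lte(m43$score, 3 / 4 + 1e-12)
})

test_that("the microstate pipeline is polarity invariant end-to-end", {
  maps <- make_test_templates(16, 4, seed = 19)
  gt <- generate_microstate_eeg(maps, 100, 40, snr = 5, seed = 20)
  neg <- eeg_record(-gt$eeg$data, 100, "common-average")
  f1 <- fit_microstates(gt$eeg, K = 4, n_restarts = 10, seed = 4)
  f2 <- fit_microstates(neg, K = 4, n_restarts = 10, seed = 4)
  expect_equal(unname(abs(diag(cor(f1$maps, f2$maps)))), rep(1, 4),
               tolerance = 1e-9)
  s1 <- segment_smooth(gt$eeg, f1)
  s2 <- segment_smooth(neg, f1)
  expect_identical(s1$labels, s2$labels)
  st1 <- microstate_stats(s1, f1, gt$eeg)
  st2 <- microstate_stats(s2, f1, neg)
  expect_equal(st1$gev, st2$gev, tolerance = 1e-12)
  expect_equal(st1$occupation_ratio, st2$occupation_ratio)
})

test_that("microstate maps round-trip through TSV", {
  model <- microstate_model(make_test_templates(10, 4, seed = 21))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_microstates_tsv(model, path)
  back <- read_microstates_tsv(path)
  expect_equal(back$maps, model$maps, tolerance = 1e-6, ignore_attr = TRUE)
})
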