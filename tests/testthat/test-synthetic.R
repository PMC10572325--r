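# seeded synthetic fixtures: spike trains, temperature traces, TRP tables

test_that("synthetic trains realize their declared composition", {
  sp <- synth_spike_train(list(list("burst", 4, 0.05), list("gap", 1),
                               list("tonic", 3, 1)))
  expect_length(sp$train$spike_times, 7)
  expect_equal(sp$bursts$n_spikes, 4)
  expect_equal(sp$tonic, 5:7)
  # pair counts as burst only when min_spikes drops to 2
  sp2 <- synth_spike_train(list(list("pair", 0.1)))
  expect_equal(nrow(sp2$bursts), 0)
  expect_equal(nrow(sp2$pairs), 1)
  expect_equal(nrow(classify_bursts(sp2$train, min_spikes = 2)$bursts), 1)
})

test_that("fixed seeds reproduce jittered trains exactly", {
  spec <- list(list("burst", 4, 0.08), list("gap", 2), list("tonic", 5, 0.8),
               list("gap", 2), list("pair", 0.1))
  a <- synth_spike_train(spec, jitter = 0.01, seed = 11)
  b <- synth_spike_train(spec, jitter = 0.01, seed = 11)
  expect_identical(a$train$spike_times, b$train$spike_times)
  c <- synth_spike_train(spec, jitter = 0.01, seed = 12)
  expect_false(identical(a$train$spike_times, c$train$spike_times))
})

test_that("ground-truth-destroying specs are refused", {
  expect_error(synth_spike_train(list(list("burst", 4, 0.19)), jitter = 0.02),
               "crosses isi_max")
  expect_error(synth_spike_train(list(list("tonic", 3, 0.21)), jitter = 0.02),
               "crosses isi_max")
  expect_error(synth_spike_train(list(list("burst", 8, 0.05)), jitter = 0.01),
               "split_over")
  expect_error(synth_spike_train(list(list("burst", 3, 0.05),
                                      list("tonic", 3, 1))),
               "explicit gap")
  expect_error(synth_spike_train(list(list("burst", 3, 0.05),
                                      list("gap", 0.1),
                                      list("tonic", 3, 1))),
               "cannot separate")
})

test_that("classifier recovers the emitted ground truth on noiseless and jittered trains", {
  set.seed(99)
  for (i in 1:40) {
    n_seg <- sample(1:5, 1)
    spec <- list()
    for (k in seq_len(n_seg)) {
      if (k > 1) spec <- c(spec, list(list("gap", runif(1, 0.5, 3))))
      spec <- c(spec, list(switch(sample(3, 1),
        list("burst", sample(3:6, 1), runif(1, 0.03, 0.15)),
        list("pair", runif(1, 0.03, 0.15)),
        list("tonic", sample(2:6, 1), runif(1, 0.3, 1.5)))))
    }
    jit <- sample(c(0, 0.005), 1)
    sp <- tryCatch(synth_spike_train(spec, jitter = jit),
                   error = function(e) NULL)
    if (is.null(sp)) next      # spec rejected by the jitter guards
    bs <- classify_bursts(sp$train)
    expect_equal(nrow(bs$bursts), nrow(sp$bursts))
    if (nrow(bs$bursts)) {
      expect_equal(bs$bursts$first, sp$bursts$first)
      expect_equal(bs$bursts$last, sp$bursts$last)
    }
    expect_equal(nrow(bs$pairs), nrow(sp$pairs))
    expect_equal(as.integer(bs$tonic), as.integer(sp$tonic))
  }
})

test_that("temperature traces follow their analytic protocol", {
  tr <- synth_temperature_trace("fast", 10, rate = 4, noise_amp = 0)
  pr <- attr(tr, "protocol")
  expect_equal(tr$temp_C,
               protocol_evaluate(pr, tr$time_s)$temperature)
  # noiseless trace reloads within the interpolation bound
  tmp <- tempfile(fileext = ".csv")
  write.csv(tr, tmp, row.names = FALSE)
  back <- load_trace(tmp)
  t <- seq(0, min(pr$total_duration, back$total_duration) - 1e-6,
           by = 0.017)
  expect_lt(max(abs(protocol_evaluate(back, t)$temperature -
                      protocol_evaluate(pr, t)$temperature)), 0.01)
  # slow trace fall duration
  sl <- synth_temperature_trace("slow", 10)
  prs <- attr(sl, "protocol")
  expect_equal(prs$segments$duration[2], 14 / 0.12)
})

test_that("trace noise is seeded, bounded and zero-mean around the protocol", {
  a <- synth_temperature_trace("trapezoid", 10, rate = 3, noise_amp = 0.05,
                               seed = 5)
  b <- synth_temperature_trace("trapezoid", 10, rate = 3, noise_amp = 0.05,
                               seed = 5)
  expect_identical(a$temp_C, b$temp_C)
  c <- synth_temperature_trace("trapezoid", 10, rate = 3, noise_amp = 0.05,
                               seed = 6)
  expect_false(identical(a$temp_C, c$temp_C))
  clean <- synth_temperature_trace("trapezoid", 10, rate = 3, noise_amp = 0)
  for (x in list(a, c)) {
    resid <- x$temp_C - clean$temp_C
    expect_lt(max(abs(mean(resid))), 3 * 0.05)
    expect_equal(sd(resid), 0.05, tolerance = 0.2)
  }
  expect_error(synth_temperature_trace("fast", noise_amp = 0.5), "0.1")
})

test_that("TRP parameter tables: exemplars plus seeded in-range draws", {
  t0 <- synth_parameter_table(0)
  expect_equal(nrow(t0), 4)
  expect_equal(t0$G_TRP_max, c(2, 1.5, 6, 1.5))
  expect_equal(t0$T_h_K, 273.15 + c(10, 8, 11, 17.5))
  a <- synth_parameter_table(50, seed = 3)
  b <- synth_parameter_table(50, seed = 3)
  expect_identical(a, b)
  big <- synth_parameter_table(2000, seed = 4)
  rng <- list(T_h_K = c(278.15, 295.15), B = c(0.2, 1), A = c(0.1, 2),
              N = c(1, 5), Ca_h = c(300, 1500), tau_hTRP = c(2, 20),
              G_TRP_max = c(0.5, 6))
  drawn <- big[-(1:4), ]
  for (nm in names(rng)) {
    expect_gte(min(drawn[[nm]]), rng[[nm]][1])
    expect_lte(max(drawn[[nm]]), rng[[nm]][2])
  }
  expect_error(synth_parameter_table(5, ranges = list(B = c(0, 2))), "B range")
})
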