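# spike detection, ISI statistics, burst segmentation, pattern labels

test_that("spike detection: threshold crossing with refractory", {
  flat <- data.frame(time = seq(0, 1, 5e-4), Vm = rep(-60, 2001))
  expect_length(detect_spikes(flat)$spike_times, 0)
  apices <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  tr <- triangle_trace(apices)
  got <- detect_spikes(tr)$spike_times
  expect_length(got, 5)
  expect_true(all(abs(got - apices) < 5e-4))
  # resampling at 10 kHz preserves count and moves times < 0.1 ms
  tr10 <- triangle_trace(apices, rate = 10000)
  got10 <- detect_spikes(tr10)$spike_times
  expect_length(got10, 5)
  expect_lt(max(abs(got - got10)), 1e-4)
  # refractory suppression of double crossings
  t <- seq(0, 0.01, 5e-5)
  wob <- data.frame(time = t, Vm = -60 + 70 * sin(2 * pi * 500 * t))
  expect_length(detect_spikes(wob, refractory = 0.01)$spike_times, 1)
})

test_that("ISIs and instantaneous frequencies", {
  f <- isi_frequency(spike_train(c(0, 0.5, 1.0)))
  expect_equal(f$isi, c(0.5, 0.5))
  expect_equal(f$freq, c(2, 2))
  expect_equal(nrow(isi_frequency(spike_train(0.3))), 0)
  f2 <- isi_frequency(spike_train(c(0, 0.1)))
  expect_equal(f2$freq, 10)
  expect_gt(f2$freq, 5)   # burst-range instantaneous frequency
})

test_that("burst rule: three or more spikes at intervals of 0.2 s or less", {
  bs <- classify_bursts(spike_train(c(0, 0.1, 0.2, 0.7, 1.9)))
  expect_equal(nrow(bs$bursts), 1)
  expect_equal(bs$bursts$n_spikes, 3)
  expect_equal(bs$bursts$start, 0)
  expect_equal(bs$bursts$end, 0.2)
  expect_equal(bs$tonic, c(4L, 5L))
  bs2 <- classify_bursts(spike_train(c(0, 0.3, 0.6)))
  expect_equal(nrow(bs2$bursts), 0)
  expect_length(bs2$tonic, 3)
  # two-spike groups are pairs under min_spikes = 3, bursts under 2
  pair <- spike_train(c(0, 0.1, 2, 2.1))
  expect_equal(nrow(classify_bursts(pair)$bursts), 0)
  expect_equal(nrow(classify_bursts(pair)$pairs), 2)
  expect_equal(nrow(classify_bursts(pair, min_spikes = 2)$bursts), 2)
})

test_that("long runs split at interior interval peaks", {
  ts <- cumsum(c(0.5, 0.05, 0.05, 0.05, 0.18, 0.05, 0.05, 0.05))
  bs <- classify_bursts(spike_train(ts))
  expect_equal(nrow(bs$bursts), 2)
  expect_equal(bs$bursts$n_spikes, c(4, 4))
  # a split that would strand a fragment below min_spikes is refused
  ts2 <- cumsum(c(0.5, 0.05, 0.12, 0.05, 0.05, 0.05, 0.05, 0.05))
  bs2 <- classify_bursts(spike_train(ts2))
  expect_equal(nrow(bs2$bursts), 1)
  expect_equal(bs2$bursts$n_spikes, 8)
  # constant intervals have no strict peak: one long burst
  ts3 <- cumsum(c(0.5, rep(0.05, 9)))
  expect_equal(classify_bursts(spike_train(ts3))$bursts$n_spikes, 10)
})

test_that("every spike is in exactly one of burst, pair, tonic", {
  set.seed(7)
  for (i in 1:50) {
    ts <- random_train(sample(4:40, 1))
    bs <- classify_bursts(spike_train(ts))
    covered <- c(unlist(lapply(seq_len(nrow(bs$bursts)), function(k)
                   seq(bs$bursts$first[k], bs$bursts$last[k]))),
                 unlist(lapply(seq_len(nrow(bs$pairs)), function(k)
                   seq(bs$pairs$first[k], bs$pairs$last[k]))),
                 bs$tonic)
    expect_identical(sort(as.integer(covered)), seq_along(ts))
  }
})

test_that("spiking rate over time windows and temperature bins", {
  tr <- spike_train(seq(0.5, 29.5, 1), window = c(0, 30))
  r <- spiking_rate(tr, window = 30)
  expect_equal(r$rate[1], 1)
  expect_equal(sum(spiking_rate(spike_train(numeric(0), window = c(0, 30)),
                                window = 10)$rate), 0)
  # temperature mode: 10 spikes while the protocol sits in one 2-degree bin
  pr <- make_trapezoid(24, 10, 1, hold_pre = 10, hold_cold = 40,
                       hold_post = 10)
  cold0 <- 10 + 14                     # cold hold starts here
  tr2 <- spike_train(cold0 + seq(1, 10), window = c(0, pr$total_duration))
  rt <- spiking_rate(tr2, window = 1, bin_mode = "temperature",
                     temp_bin = 2, protocol = pr)
  bin10 <- rt[rt$temp_left == 10, ]
  expect_equal(bin10$rate, 10 / bin10$time_in_bin)
  expect_error(spiking_rate(tr2, bin_mode = "temperature"), "protocol")
})

test_that("burst occurrence rate bins by first-spike time with composition", {
  ts <- c(0, 0.1, 0.2,               # 3-spike burst at 0
          5, 5.1, 5.2, 5.3, 5.45,    # 5-spike burst at 5
          9.9, 10.05,                # pair straddling the bin edge
          12)                        # tonic spike
  bs <- classify_bursts(spike_train(ts, window = c(0, 20)))
  br <- burst_occurrence_rate(bs, bins = 10)
  expect_equal(br$rate[1], 0.2)       # both bursts start in [0, 10)
  expect_equal(br$rate[2], 0)
  expect_equal(br$n2[1], 1)           # pair counted where its first spike is
  expect_equal(br$n3[1], 1)
  expect_equal(br$n4plus[1], 1)
  ts3 <- c(1, 1.1, 1.2, 3, 3.1, 3.2, 7, 7.1, 7.2)
  bs3 <- classify_bursts(spike_train(ts3, window = c(0, 10)))
  expect_equal(burst_occurrence_rate(bs3, bins = 10)$rate[1], 0.3)
})

test_that("pattern labels: silence, bursting, period-2, tonic", {
  expect_equal(suppressWarnings(
    classify_pattern(spike_train(numeric(0), window = c(0, 10))))$label,
    "silence")
  b <- classify_pattern(spike_train(c(0, 0.1, 0.2, 0.7, 1.9),
                                    window = c(0, 10)))
  expect_equal(b$label, "bursting")
  # alternating short/long intervals with no 3-spike run: period-2
  isis <- rep(c(0.3, 0.1), 10)
  p2 <- classify_pattern(spike_train(cumsum(c(0.5, isis)), window = c(0, 10)))
  expect_equal(p2$label, "period2")
  ton <- classify_pattern(spike_train(seq(0.5, 9.5, 1), window = c(0, 10)))
  expect_equal(ton$label, "tonic")
  # smoothly accelerating spiking crossing the 0.2 s line stays tonic
  # (window truncated at the last spike, as on a falling-phase excerpt)
  acc <- cumsum(c(0.5, seq(0.4, 0.05, length.out = 30)))
  expect_equal(classify_pattern(spike_train(acc,
                                            window = c(0, max(acc))))$label,
               "tonic")
})

test_that("depolarization block and plateau need the voltage trace", {
  t <- seq(0, 40, 5e-4)
  # spikes early, then a sustained depolarized tail: block
  v <- ifelse(t < 10, -50 + 60 * (sin(2 * pi * t) > 0.99), -20)
  blk <- list(data = data.frame(time = t, Vm = v))
  class(blk) <- "simulation_result"
  train <- detect_spikes(blk)
  lab <- classify_pattern(train, trace = blk)
  expect_equal(lab$label, "depol_block")
  # depolarized envelope that later repolarizes: plateau
  v2 <- ifelse(t < 10, -50 + 60 * (sin(2 * pi * t) > 0.99),
               ifelse(t < 25, -20, -55))
  pla <- list(data = data.frame(time = t, Vm = v2))
  class(pla) <- "simulation_result"
  lab2 <- classify_pattern(detect_spikes(pla), trace = pla)
  expect_equal(lab2$label, "plateau")
})

test_that("short analysis windows warn and classification is trace-sampling safe", {
  expect_warning(classify_pattern(spike_train(c(0.1, 0.2), window = c(0, 1))),
                 "low-confidence")
  # adding subthreshold samples between spikes does not change the label
  tr <- triangle_trace(c(0.5, 0.65, 0.8, 2.5), t_end = 8)
  l1 <- classify_pattern(detect_spikes(tr))
  tr2 <- triangle_trace(c(0.5, 0.65, 0.8, 2.5), rate = 10000, t_end = 8)
  l2 <- classify_pattern(detect_spikes(tr2))
  expect_identical(l1$label, l2$label)
  expect_identical(l1$label, "bursting")
})

test_that("phase statistics split a run into the standard phases", {
  pr <- make_experimental_like("fast", 10, initial_rate = 4,
                               hold_pre = 30, hold_cold = 60)
  # six bursts in the 30 s fall phase, nothing later
  segs <- list()
  t0 <- 31
  ts <- unlist(lapply(0:5, function(k) t0 + 4 * k + c(0, 0.05, 0.1)))
  train <- spike_train(ts, window = c(0, pr$total_duration))
  tab <- phase_statistics(train, protocol = pr, scheme = "fast")
  expect_equal(tab$burst_rate[tab$phase == "fall_a"], 0.2)
  expect_equal(tab$burst_rate[tab$phase == "steady_b"], 0)
  expect_equal(tab$burst_rate[tab$phase == "delta_ab"], 0.2)
  expect_equal(tab$tonic_freq[tab$phase == "fall_a"], 0)
  # spikes entirely in phase b leave phase a empty
  train_b <- spike_train(seq(62, 80, 2), window = c(0, pr$total_duration))
  tab_b <- phase_statistics(train_b, protocol = pr, scheme = "fast")
  expect_equal(tab_b$tonic_freq[tab_b$phase == "fall_a"], 0)
  expect_gt(tab_b$tonic_freq[tab_b$phase == "steady_b"], 0)
  # empty train: all-zero table
  tab_e <- phase_statistics(spike_train(numeric(0),
                                        window = c(0, pr$total_duration)),
                            protocol = pr, scheme = "fast")
  expect_true(all(tab_e$burst_rate == 0) && all(tab_e$tonic_freq == 0))
  # slow scheme needs 120 + 30 s after onset
  expect_error(phase_statistics(train, protocol = pr, scheme = "slow"),
               "too short")
})

test_that("spike train and burst tables round-trip through CSV", {
  ts <- c(0, 0.1, 0.2, 0.7, 1.9)
  tmp <- tempfile(fileext = ".csv")
  write_spike_train(spike_train(ts), tmp)
  expect_equal(read_spike_train(tmp)$spike_times, ts)
  bs <- classify_bursts(spike_train(ts))
  tmp2 <- tempfile(fileext = ".csv")
  write_burst_table(bs, tmp2)
  tab <- read.csv(tmp2)
  expect_equal(tab$n_spikes, 3)
  expect_equal(tab$start_s, 0)
})
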