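#' Spike trains
#'
#' A `spike_train` holds sorted spike times (s) together with the analysis
#' window and a source tag.  Trains come from [detect_spikes()] on
#' simulated voltage, from [synth_spike_train()], or from a file.
#'
#' @param spike_times numeric vector of spike times (s).
#' @param window length-2 numeric `(t0, t1)`; defaults to the span of the
#'   times.
#' @param source `"model"`, `"synthetic"` or `"file"`.
#' @return a `spike_train`.
#' @export
spike_train <- function(spike_times, window = NULL, source = "model") {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (is.null(window))
    window <- if (length(spike_times)) range(spike_times) else c(0, 0)
  structure(list(spike_times = spike_times, window = window, source = source),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train (%s): %d spikes in [%.2f, %.2f] s\n",
              x$source, length(x$spike_times), x$window[1], x$window[2]))
  invisible(x)
}

#' Detect spikes in a simulated voltage trace
#'
#' A spike is an upward crossing of the voltage threshold (default 0 mV),
#' timed by linear interpolation between the bracketing samples; further
#' crossings within the refractory window are ignored.  The trace must be
#' sampled densely enough to resolve spikes (>= 2 kHz by default
#' elsewhere in the package).
#'
#' @param result a `simulation_result` (or a data frame with `time` and
#'   `Vm` columns).
#' @param threshold crossing threshold (mV), default 0.
#' @param refractory dead time after an accepted spike (s), default 1 ms.
#' @return a `spike_train`.
#' @export
detect_spikes <- function(result, threshold = 0, refractory = 0.001) {
  d <- if (inherits(result, "simulation_result")) result$data else result
  if (nrow(d) == 0)
    return(spike_train(numeric(0), window = c(0, 0), source = "model"))
  v <- d$Vm; t <- d$time
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  times <- t[up] + (threshold - v[up]) / (v[up + 1] - v[up]) * (t[up + 1] - t[up])
  if (length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (i in seq_along(times)[-1]) {
      if (times[i] - last < refractory) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]
  }
  spike_train(times, window = range(t), source = "model")
}

#' Interspike intervals and instantaneous frequencies
#'
#' `ISI_k = t_{k+1} - t_k` and `f_k = 1/ISI_k`, one row per consecutive
#' spike pair.
#'
#' @param train a `spike_train`.
#' @return data frame with columns `t_prev`, `t_next`, `isi` (s) and
#'   `freq` (Hz); zero rows for fewer than two spikes.
#' @examples
#' isi_frequency(spike_train(c(0, 0.5, 1)))
#' @export
isi_frequency <- function(train) {
  ts <- train$spike_times
  if (length(ts) < 2)
    return(data.frame(t_prev = numeric(0), t_next = numeric(0),
                      isi = numeric(0), freq = numeric(0)))
  isi <- diff(ts)
  data.frame(t_prev = ts[-length(ts)], t_next = ts[-1],
             isi = isi, freq = 1 / isi)
}

#' Segment a spike train into bursts
#'
#' A burst is a series of `min_spikes` (default 3) or more spikes whose
#' consecutive interspike intervals are all `isi_max` (default 0.2 s) or
#' less.  When a short-ISI run contains more than `split_over` (default 6)
#' spikes, interior strict local maxima of its ISI sequence are treated as
#' breaks between bursts: candidate peaks are applied greedily from the
#' largest downward (ties towards the earlier peak), rejecting any split
#' that would leave a fragment with fewer than `min_spikes` spikes.
#' Two-spike short-ISI groups are tallied separately as pairs and are not
#' counted as bursts under the default `min_spikes = 3`; spikes in no
#' short-ISI group are tonic.
#'
#' @param train a `spike_train`.
#' @param isi_max maximal intra-burst interval (s).
#' @param min_spikes minimal spikes per burst (set 2 to count pairs as
#'   bursts).
#' @param split_over run length above which peak-splitting applies.
#' @return a `burst_set`: list with `bursts` (data frame: `burst_id`,
#'   `first`, `last` spike indices, `start`, `end`, `n_spikes`,
#'   `duration`, `mean_freq`), `pairs` (two-spike groups, same layout),
#'   `tonic` (indices of tonic spikes), the parameters, and the `train`.
#' @examples
#' bs <- classify_bursts(spike_train(c(0, 0.1, 0.2, 0.7, 1.9)))
#' bs$bursts$n_spikes  # 3
#' @export
classify_bursts <- function(train, isi_max = 0.2, min_spikes = 3,
                            split_over = 6) {
  ts <- train$spike_times
  n <- length(ts)
  groups <- list()     # integer index ranges of final burst groups
  pairs <- list()
  in_group <- rep(FALSE, n)
  if (n >= 2) {
    short <- diff(ts) <= isi_max
    r <- rle(short)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      i0 <- starts[j]; i1 <- ends[j] + 1   # spike indices of the run
      size <- i1 - i0 + 1
      if (size == 2 && min_spikes > 2) {
        pairs[[length(pairs) + 1]] <- c(i0, i1)
        in_group[i0:i1] <- TRUE
        next
      }
      if (size < min_spikes) next
      frs <- if (size > split_over)
        split_run(ts[i0:i1], min_spikes) else list(c(1, size))
      for (fr in frs)
        groups[[length(groups) + 1]] <- c(i0 + fr[1] - 1, i0 + fr[2] - 1)
      in_group[i0:i1] <- TRUE
    }
  }
  mk <- function(lst) {
    if (!length(lst))
      return(data.frame(burst_id = integer(0), first = integer(0),
                        last = integer(0), start = numeric(0),
                        end = numeric(0), n_spikes = integer(0),
                        duration = numeric(0), mean_freq = numeric(0)))
    do.call(rbind, lapply(seq_along(lst), function(k) {
      g <- lst[[k]]
      tt <- ts[g[1]:g[2]]
      data.frame(burst_id = k, first = g[1], last = g[2],
                 start = tt[1], end = tt[length(tt)],
                 n_spikes = length(tt), duration = tt[length(tt)] - tt[1],
                 mean_freq = mean(1 / diff(tt)))
    }))
  }
  structure(list(bursts = mk(groups), pairs = mk(pairs),
                 tonic = which(!in_group),
                 params = list(isi_max = isi_max, min_spikes = min_spikes,
                               split_over = split_over),
                 train = train),
            class = "burst_set")
}

# split one long short-ISI run at interior strict local ISI maxima,
# greedily from the largest peak; returns list of (first, last) local
# spike-index fragments.  Peaks must exceed their neighbors by a
# nanosecond guard so that float noise on constant intervals does not
# manufacture breaks.
split_run <- function(tt, min_spikes, eps = 1e-9) {
  m <- length(tt)
  isi <- diff(tt)                       # isi i sits between spikes i, i+1
  interior <- seq_along(isi)[-c(1, length(isi))]
  peaks <- interior[isi[interior] > isi[interior - 1] + eps &
                    isi[interior] > isi[interior + 1] + eps]
  if (!length(peaks)) return(list(c(1, m)))
  peaks <- peaks[order(-isi[peaks], peaks)]   # largest first, ties earlier
  breaks <- integer(0)                  # split after spike index k
  for (pk in peaks) {
    bs <- sort(c(0, breaks, m))
    lo <- max(bs[bs < pk]); hi <- min(bs[bs >= pk + 1])
    # fragment currently containing the peak spans spikes (lo+1)..hi
    if (pk - lo >= min_spikes && hi - pk >= min_spikes)
      breaks <- c(breaks, pk)
  }
  bs <- sort(c(0, breaks, m))
  lapply(seq_len(length(bs) - 1), function(i) c(bs[i] + 1, bs[i + 1]))
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("Burst set: %d bursts, %d two-spike pairs, %d tonic spikes\n",
              nrow(x$bursts), nrow(x$pairs), length(x$tonic)))
  invisible(x)
}

# ISIs lying inside qualifying bursts
intra_burst_isis <- function(train, bursts) {
  ts <- train$spike_times
  b <- bursts$bursts
  if (!nrow(b)) return(numeric(0))
  unlist(lapply(seq_len(nrow(b)), function(k) diff(ts[b$first[k]:b$last[k]])))
}

#' Average spiking rate over fixed bins
#'
#' Spike count divided by bin width, over either fixed time windows or
#' fixed-width temperature bins (spikes assigned by the protocol
#' temperature at their time, rate normalized by time spent in the bin).
#'
#' @param train a `spike_train`.
#' @param window bin width (s) in time mode.
#' @param bin_mode `"time"` or `"temperature"`.
#' @param temp_bin temperature bin width (deg C), default 2.
#' @param protocol required in temperature mode.
#' @return data frame of bins and rates (spikes/s).
#' @export
spiking_rate <- function(train, window = 30, bin_mode = c("time", "temperature"),
                         temp_bin = 2, protocol = NULL) {
  bin_mode <- match.arg(bin_mode)
  if (window <= 0) stop("window must be > 0")
  ts <- train$spike_times
  if (bin_mode == "time") {
    edges <- seq(train$window[1], train$window[2] + window, by = window)
    counts <- tabulate(findInterval(ts, edges, rightmost.closed = FALSE),
                       nbins = length(edges) - 1)
    return(data.frame(t_left = edges[-length(edges)],
                      t_right = edges[-1],
                      rate = counts / window))
  }
  if (is.null(protocol))
    stop("temperature binning requires a protocol")
  dt <- 0.01
  tg <- seq(train$window[1], train$window[2], by = dt)
  temps <- protocol_evaluate(protocol, tg)$temperature
  lo <- floor(min(temps) / temp_bin) * temp_bin
  edges <- seq(lo, max(temps) + temp_bin, by = temp_bin)
  occupancy <- tabulate(findInterval(temps, edges), nbins = length(edges) - 1) * dt
  st <- protocol_evaluate(protocol, ts[ts >= train$window[1] &
                                         ts <= train$window[2]])$temperature
  counts <- tabulate(findInterval(st, edges), nbins = length(edges) - 1)
  keep <- occupancy > 0
  data.frame(temp_left = edges[-length(edges)][keep],
             temp_right = edges[-1][keep],
             time_in_bin = occupancy[keep],
             rate = counts[keep] / occupancy[keep])
}

#' Burst occurrence rate per time bin
#'
#' Bursts are assigned to bins by their first-spike time; the rate is the
#' count divided by the bin width.  The per-bin composition by burst size
#' (two-spike pairs, three-spike bursts, four or more) is reported
#' alongside.
#'
#' @param bursts a `burst_set`.
#' @param bins bin width (s).
#' @return data frame with `t_left`, `t_right`, `rate` (bursts/s; pairs
#'   excluded), and composition counts `n2`, `n3`, `n4plus`.
#' @export
burst_occurrence_rate <- function(bursts, bins = 10) {
  if (bins <= 0) stop("bin width must be > 0")
  w <- bursts$train$window
  edges <- seq(w[1], w[2] + bins, by = bins)
  nb <- length(edges) - 1
  b <- bursts$bursts; p <- bursts$pairs
  nall <- tabulate(findInterval(b$start, edges), nbins = nb)
  n3 <- tabulate(findInterval(b$start[b$n_spikes == 3], edges), nbins = nb)
  n4 <- tabulate(findInterval(b$start[b$n_spikes >= 4], edges), nbins = nb)
  n2 <- tabulate(findInterval(p$start, edges), nbins = nb)
  data.frame(t_left = edges[-length(edges)], t_right = edges[-1],
             rate = nall / bins, n2 = n2, n3 = n3, n4plus = n4)
}

#' Classify the activity pattern of an analysis window
#'
#' Assigns exactly one label: `silence` (no spikes); `depol_block`
#' (spikes occurred but the final 5 s are spikeless with mean Vm above
#' -30 mV); `plateau` (after the last spike the membrane stays above
#' -30 mV for more than 5 s and then repolarizes before the window ends);
#' `bursting` (at least one contrasted burst, see below); `period2` (no
#' bursts, ISIs alternating between two levels: the median of
#' |ISI_{k+2} - ISI_k| is below 5% of the mean ISI while the median of
#' |ISI_{k+1} - ISI_k| exceeds 10%); otherwise `tonic`.  The
#' depolarization thresholds (-30 mV, 5 s) operationalize labels the
#' experimental literature names but does not define numerically.
#'
#' A burst counts as evidence of a bursting pattern only when it stands
#' out from its surroundings: the interspike interval immediately before
#' or after the burst must be a pause (> `isi_max`) at least `contrast`
#' times the burst's mean intra-burst interval.  This is the
#' interval-bimodality signature of bursting responses; without the
#' contrast requirement, smoothly accelerating tonic spiking whose
#' intervals drift below `isi_max` would be mislabeled as bursting.
#'
#' @param train a `spike_train`.
#' @param bursts optional `burst_set` (recomputed if missing).
#' @param trace optional `simulation_result` supplying Vm, required for
#'   the `depol_block`/`plateau` labels.
#' @param isi_max burst interval threshold (s).
#' @param contrast minimal pause-to-intra-burst interval ratio for a
#'   burst to label the window as bursting.
#' @return a `pattern_label`: list with `label` and the `evidence` used.
#' @examples
#' classify_pattern(spike_train(c(0, 0.1, 0.2, 0.7, 1.9, 6)))$label
#' @export
classify_pattern <- function(train, bursts = NULL, trace = NULL,
                             isi_max = 0.2, contrast = 2) {
  if (is.null(bursts)) bursts <- classify_bursts(train, isi_max = isi_max)
  ts <- train$spike_times
  w <- train$window
  if (diff(w) < 5)
    warning("analysis window shorter than 5 s; steady-state label is low-confidence")
  ev <- list(n_spikes = length(ts), n_bursts = nrow(bursts$bursts))
  lab <- NULL
  if (!length(ts)) lab <- "silence"
  if (is.null(lab) && !is.null(trace)) {
    d <- trace$data
    t_end <- max(d$time)
    last5 <- d$Vm[d$time >= t_end - 5]
    ev$mean_Vm_last5 <- mean(last5)
    if (!any(ts >= t_end - 5) && mean(last5) > -30) {
      lab <- "depol_block"
    } else if (length(ts)) {
      after <- d[d$time > max(ts), , drop = FALSE]
      if (nrow(after) > 2) {
        above <- after$Vm > -30
        if (any(above)) {
          # longest depolarized stretch after the last spike, then recovery
          r <- rle(above)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1
          for (j in seq_along(r$values)) {
            if (!r$values[j]) next
            dur <- after$time[ends[j]] - after$time[starts[j]]
            repol <- ends[j] < nrow(after)
            if (dur > 5 && repol) { lab <- "plateau"; break }
          }
        }
      }
    }
  }
  isi <- diff(ts)
  if (is.null(lab)) {
    nq <- n_contrasted_bursts(train, bursts, isi_max, contrast)
    ev$n_contrasted_bursts <- nq
    if (nq >= 1) {
      lab <- "bursting"
    } else if (length(isi) >= 5) {
      m <- mean(isi)
      d1 <- stats::median(abs(diff(isi)))
      d2 <- stats::median(abs(isi[-(1:2)] - isi[seq_len(length(isi) - 2)]))
      ev$alt_d1 <- d1 / m; ev$alt_d2 <- d2 / m
      if (nrow(bursts$bursts) == 0 && d2 < 0.05 * m && d1 > 0.10 * m)
        lab <- "period2"
    }
  }
  if (is.null(lab)) lab <- "tonic"
  structure(list(label = lab, evidence = ev), class = "pattern_label")
}

# bursts that stand out against their surroundings: the ISI immediately
# before (after) the burst is a pause (> isi_max) at least `contrast`
# times the intra-burst ISI adjacent to it.  The comparison is local --
# against the neighboring intra-burst interval, not the run mean -- so a
# long, smoothly accelerating tonic stretch whose first interval happens
# to exceed isi_max does not register as a burst.
n_contrasted_bursts <- function(train, bursts, isi_max = 0.2, contrast = 2) {
  b <- bursts$bursts
  if (!nrow(b)) return(0L)
  ts <- train$spike_times
  ok <- vapply(seq_len(nrow(b)), function(k) {
    intra <- diff(ts[b$first[k]:b$last[k]])
    pre <- if (b$first[k] > 1) ts[b$first[k]] - ts[b$first[k] - 1] else NA
    # observed silence after the last spike counts as a pause (burst
    # termination); silence before the first spike does not (it is the
    # approach to threshold, not a pause between activity)
    post <- if (b$last[k] < length(ts)) ts[b$last[k] + 1] - ts[b$last[k]]
            else train$window[2] - ts[b$last[k]]
    (isTRUE(pre > isi_max && pre >= contrast * intra[1])) ||
      (isTRUE(post > isi_max && post >= contrast * intra[length(intra)]))
  }, NA)
  sum(ok)
}

#' @export
print.pattern_label <- function(x, ...) {
  cat("Activity pattern:", x$label, "\n")
  invisible(x)
}

#' Per-phase burst and tonic-spike statistics
#'
#' Splits a protocol run into the conventional analysis phases --
#' pre-stimulus, temperature drop (a), steady cold (b), temperature rise,
#' and post-stimulus -- and reports the burst occurrence rate and tonic
#' spike frequency in each.  The drop/steady boundaries are 30 s / 30 s
#' for the fast scheme and 120 s / 30 s for the slow scheme, counted from
#' stimulus onset.  The difference a - b used for rate-correlation plots
#' is appended.
#'
#' @param train a `spike_train` covering the run.
#' @param bursts a `burst_set` for the train (recomputed if `NULL`).
#' @param protocol the `temperature_protocol` of the run.
#' @param scheme `"fast"` (30 s drop phase) or `"slow"` (120 s).
#' @return data frame with one row per phase (`phase`, `t0`, `t1`,
#'   `burst_rate` bursts/s, `tonic_freq` spikes/s) plus a `"delta_ab"`
#'   row.
#' @export
phase_statistics <- function(train, bursts = NULL, protocol,
                             scheme = c("fast", "slow")) {
  scheme <- match.arg(scheme)
  if (is.null(bursts)) bursts <- classify_bursts(train)
  da <- if (scheme == "fast") 30 else 120
  onset <- protocol_onset(protocol)
  if (protocol$total_duration < onset + da + 30)
    stop("protocol too short for the ", scheme, " phase scheme")
  a0 <- onset; a1 <- onset + da; b1 <- a1 + 30
  # end of the rising leg: temperature back within 0.5 degC of start
  tg <- seq(b1, protocol$total_duration, by = 0.1)
  tv <- protocol_evaluate(protocol, tg)$temperature
  t_start <- protocol_start_temp(protocol)
  ir <- which(tv >= t_start - 0.5)
  r1 <- if (length(ir)) tg[ir[1]] else protocol$total_duration
  phases <- data.frame(
    phase = c("pre", "fall_a", "steady_b", "rise", "post"),
    t0 = c(0, a0, a1, b1, r1),
    t1 = c(a0, a1, b1, r1, protocol$total_duration))
  phases <- phases[phases$t1 > phases$t0, ]
  ts <- train$spike_times
  bstart <- bursts$bursts$start
  intra <- unlist(lapply(seq_len(nrow(bursts$bursts)), function(k)
    seq(bursts$bursts$first[k], bursts$bursts$last[k])))
  pairsp <- unlist(lapply(seq_len(nrow(bursts$pairs)), function(k)
    seq(bursts$pairs$first[k], bursts$pairs$last[k])))
  tonic_times <- ts[setdiff(seq_along(ts), c(intra, pairsp))]
  phases$burst_rate <- vapply(seq_len(nrow(phases)), function(i) {
    sum(bstart >= phases$t0[i] & bstart < phases$t1[i]) /
      (phases$t1[i] - phases$t0[i])
  }, 0)
  phases$tonic_freq <- vapply(seq_len(nrow(phases)), function(i) {
    sum(tonic_times >= phases$t0[i] & tonic_times < phases$t1[i]) /
      (phases$t1[i] - phases$t0[i])
  }, 0)
  d <- data.frame(phase = "delta_ab", t0 = NA, t1 = NA,
                  burst_rate = phases$burst_rate[phases$phase == "fall_a"] -
                    phases$burst_rate[phases$phase == "steady_b"],
                  tonic_freq = phases$tonic_freq[phases$phase == "fall_a"] -
                    phases$tonic_freq[phases$phase == "steady_b"])
  rbind(phases, d)
}

#' Read and write spike-train and burst CSV files
#'
#' Spike trains are stored as a one-column CSV (`spike_time_s`); burst
#' tables with columns `burst_id`, `start_s`, `end_s`, `n_spikes`,
#' `mean_freq_hz`.
#'
#' @param train a `spike_train`; `bursts` a `burst_set`; `path` a file.
#' @return readers return the object; writers the path, invisibly.
#' @export
write_spike_train <- function(train, path) {
  utils::write.csv(data.frame(spike_time_s = train$spike_times), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- utils::read.csv(path)
  spike_train(df[[1]], source = "file")
}

#' @rdname write_spike_train
#' @param bursts a `burst_set`.
#' @export
write_burst_table <- function(bursts, path) {
  b <- bursts$bursts
  utils::write.csv(data.frame(burst_id = b$burst_id, start_s = b$start,
                              end_s = b$end, n_spikes = b$n_spikes,
                              mean_freq_hz = b$mean_freq),
                   path, row.names = FALSE)
  invisible(path)
}
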