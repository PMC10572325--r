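#' Synthetic spike trains with known burst composition
#'
#' Builds a spike train from a declarative list of segments, each one of
#' \describe{
#'   \item{burst}{`list("burst", n, isi)`: `n >= 3` spikes at interval
#'     `isi <= isi_max`.}
#'   \item{pair}{`list("pair", isi)`: two spikes at a short interval.}
#'   \item{tonic}{`list("tonic", n, isi)`: `n` spikes at `isi > isi_max`.}
#'   \item{gap}{`list("gap", duration)`: silent period separating
#'     segments (must exceed `isi_max`).}
#' }
#' together with the exact burst segmentation that [classify_bursts()]
#' must recover (the ground truth serves as the classifier oracle).
#' Optional uniform jitter is applied to every spike time; the
#' construction refuses jitter large enough to blur the regime
#' boundaries (intervals crossing `isi_max`, or a peak appearing inside
#' a constant-interval long burst).
#'
#' @param segments list of segment descriptors as above.
#' @param jitter half-width of the uniform time jitter (s).
#' @param seed RNG seed for the jitter.
#' @param isi_max,min_spikes,split_over the burst-rule parameters the
#'   ground truth is computed for.
#' @param t0 start time of the first segment (s).
#' @return list with `train` (a `spike_train`), `bursts`, `pairs` (data
#'   frames of first/last spike indices), and `tonic` (spike indices).
#' @examples
#' sp <- synth_spike_train(list(list("burst", 4, 0.05), list("gap", 1),
#'                              list("tonic", 3, 1)))
#' length(sp$train$spike_times)  # 7
#' @export
synth_spike_train <- function(segments, jitter = 0, seed = NULL,
                              isi_max = 0.2, min_spikes = 3, split_over = 6,
                              t0 = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (jitter < 0) stop("jitter must be >= 0")
  times <- numeric(0)
  kind_of <- integer(0)       # ground-truth group id per spike; 0 = tonic
  grp <- list()               # group kind per id: "burst" or "pair"
  t <- t0
  prev_spiking <- FALSE
  for (sg in segments) {
    kind <- sg[[1]]
    if (kind == "gap") {
      dur <- sg[[2]]
      if (dur - 2 * jitter <= isi_max)
        stop("gap of ", dur, " s cannot separate regimes with jitter ", jitter)
      t <- t + dur
      prev_spiking <- FALSE
      next
    }
    if (prev_spiking)
      stop("spiking segments must be separated by an explicit gap")
    if (kind == "burst") {
      n <- sg[[2]]; isi <- sg[[3]]
      if (n < min_spikes) stop("burst segments need >= min_spikes spikes")
      if (isi + 2 * jitter > isi_max)
        stop("burst interval ", isi, " + jitter crosses isi_max")
      if (isi - 2 * jitter <= 0)
        stop("jitter larger than half the burst interval reorders spikes")
      if (n > split_over && jitter > 0)
        stop("jitter would create interval peaks inside a long burst; ",
             "use jitter = 0 for bursts longer than split_over")
      tt <- t + isi * (seq_len(n) - 1)
      grp[[length(grp) + 1]] <- "burst"
      kk <- rep(length(grp), n)
    } else if (kind == "pair") {
      isi <- sg[[2]]
      if (isi + 2 * jitter > isi_max)
        stop("pair interval + jitter crosses isi_max")
      if (isi - 2 * jitter <= 0)
        stop("jitter larger than half the pair interval reorders spikes")
      tt <- t + c(0, isi)
      grp[[length(grp) + 1]] <- "pair"
      kk <- rep(length(grp), 2)
    } else if (kind == "tonic") {
      n <- sg[[2]]; isi <- sg[[3]]
      if (isi - 2 * jitter <= isi_max)
        stop("tonic interval ", isi, " - jitter crosses isi_max")
      tt <- t + isi * (seq_len(n) - 1)
      kk <- rep(0L, n)
    } else stop("unknown segment kind: ", kind)
    times <- c(times, tt)
    kind_of <- c(kind_of, kk)
    t <- max(tt)
    prev_spiking <- TRUE
  }
  if (!length(times)) stop("no spikes generated")
  if (jitter > 0) times <- times + stats::runif(length(times), -jitter, jitter)
  ord <- order(times)
  stopifnot(identical(ord, seq_along(times)))  # jitter checks guarantee order
  mk <- function(sel_kind) {
    ids <- which(unlist(grp) == sel_kind)
    if (!length(ids))
      return(data.frame(first = integer(0), last = integer(0),
                        n_spikes = integer(0)))
    do.call(rbind, lapply(ids, function(id) {
      w <- which(kind_of == id)
      data.frame(first = min(w), last = max(w), n_spikes = length(w))
    }))
  }
  list(train = spike_train(times, source = "synthetic"),
       bursts = mk("burst"), pairs = mk("pair"),
       tonic = which(kind_of == 0L))
}

#' Synthetic thermocouple-like temperature traces
#'
#' Samples an analytic protocol (fast exponential, slow ramp or
#' trapezoid) on a regular grid and optionally adds seeded, low-pass
#' filtered Gaussian noise to emulate a recorded thermometer trace.  The
#' result is a data frame loadable through [protocol_from_trace()] (or
#' writable with [utils::write.csv()] and reloadable with
#' [load_trace()]).
#'
#' @param kind `"fast"`, `"slow"` or `"trapezoid"`.
#' @param T_target cold target temperature (deg C).
#' @param rate initial cooling rate (fast, deg C/s) or ramp rate
#'   (trapezoid).
#' @param T_room starting temperature (deg C).
#' @param noise_amp noise amplitude (deg C, standard deviation scale);
#'   at most 0.1.
#' @param seed RNG seed for the noise.
#' @param rate_hz sampling rate (Hz), default 100 (thermometer
#'   bandwidth, far below the electrophysiology rate -- temperature is
#'   slow).
#' @return data frame with `time_s` and `temp_C`, plus the generating
#'   protocol as attribute `"protocol"`.
#' @export
synth_temperature_trace <- function(kind = c("fast", "slow", "trapezoid"),
                                    T_target = 10, rate = 4, T_room = 24,
                                    noise_amp = 0, seed = NULL,
                                    rate_hz = 100) {
  kind <- match.arg(kind)
  if (noise_amp > 0.1) stop("noise amplitude must be <= 0.1 degC")
  pr <- switch(kind,
    fast = make_experimental_like("fast", T_target, initial_rate = rate,
                                  T_room = T_room),
    slow = make_experimental_like("slow", T_target, T_room = T_room),
    trapezoid = make_trapezoid(T_room, T_target, rate))
  t <- seq(0, pr$total_duration, by = 1 / rate_hz)
  temp <- protocol_evaluate(pr, t)$temperature
  if (noise_amp > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- stats::rnorm(length(t))
    # first-order low-pass, ~1 s time constant at the sampling rate
    alpha <- 1 / rate_hz
    sm <- stats::filter(w, 1 - alpha, method = "recursive")
    sm <- as.numeric(sm) / stats::sd(sm) * noise_amp
    temp <- temp + sm
  }
  out <- data.frame(time_s = t, temp_C = temp)
  attr(out, "protocol") <- pr
  out
}

# TRP parameter sets of the four worked level-II examples (activation
# scaling B and tau_mTRP keep the reference defaults)
exemplar_trp_table <- function() {
  data.frame(
    set_id = c("exemplar_A", "exemplar_B", "exemplar_C", "exemplar_D"),
    G_TRP_max = c(2, 1.5, 6, 1.5),
    A = c(0.5, 0.5, 0.3, 0.25),
    B = 1,
    N = c(5, 5, 5, 1),
    T_h_K = celsius_to_kelvin(c(10, 8, 11, 17.5)),
    Ca_h = c(500, 500, 500, 300),
    tau_hTRP = c(5, 5, 15, 15),
    tau_mTRP = 0.002,
    stringsAsFactors = FALSE
  )
}

#' Synthetic TRP parameter tables for the phenotype census
#'
#' Emits the four fixed exemplar parameter sets (the worked level-II
#' examples) followed by `n` seeded uniform draws from the given ranges.
#' The table is the input format of [phenotype_census()].
#'
#' @param n number of random rows (0 gives only the exemplars).
#' @param ranges named list of length-2 numeric ranges for any of
#'   `T_h_K`, `B`, `A`, `N`, `Ca_h`, `tau_hTRP`, `G_TRP_max`.
#' @param seed RNG seed.
#' @return data frame with columns `set_id`, `G_TRP_max`, `A`, `B`,
#'   `N`, `T_h_K`, `Ca_h`, `tau_hTRP`, `tau_mTRP`.
#' @export
synth_parameter_table <- function(n = 0,
                                  ranges = list(T_h_K = c(278.15, 295.15),
                                                B = c(0.2, 1),
                                                A = c(0.1, 2),
                                                N = c(1, 5),
                                                Ca_h = c(300, 1500),
                                                tau_hTRP = c(2, 20),
                                                G_TRP_max = c(0.5, 6)),
                                  seed = NULL) {
  defaults <- list(T_h_K = c(278.15, 295.15), B = c(0.2, 1), A = c(0.1, 2),
                   N = c(1, 5), Ca_h = c(300, 1500), tau_hTRP = c(2, 20),
                   G_TRP_max = c(0.5, 6))
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad)) stop("unknown range name(s): ", paste(bad, collapse = ", "))
  defaults[names(ranges)] <- ranges
  ranges <- defaults
  if (any(ranges$B <= 0) || any(ranges$B > 1)) stop("B range must lie in (0, 1]")
  if (any(ranges$A <= 0)) stop("A range must be positive")
  if (any(ranges$N < 1)) stop("N range must be >= 1")
  if (any(ranges$Ca_h <= 0) || any(ranges$tau_hTRP <= 0) ||
      any(ranges$G_TRP_max < 0) || any(ranges$T_h_K <= 0))
    stop("ranges must be within physical bounds")
  tab <- exemplar_trp_table()
  if (n > 0) {
    if (!is.null(seed)) set.seed(seed)
    draw <- function(r, n) stats::runif(n, min(r), max(r))
    rnd <- data.frame(
      set_id = sprintf("draw_%04d", seq_len(n)),
      G_TRP_max = draw(ranges$G_TRP_max, n),
      A = draw(ranges$A, n),
      B = draw(ranges$B, n),
      N = draw(ranges$N, n),
      T_h_K = draw(ranges$T_h_K, n),
      Ca_h = draw(ranges$Ca_h, n),
      tau_hTRP = draw(ranges$tau_hTRP, n),
      tau_mTRP = 0.002,
      stringsAsFactors = FALSE
    )
    tab <- rbind(tab, rnd)
  }
  tab
}
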