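#' Temperature stimulation protocols
#'
#' A `temperature_protocol` is a piecewise description of the bath
#' temperature over time, either analytic (ordered hold / linear /
#' exponential segments) or a recorded trace replayed by linear
#' interpolation.  Analytic segments are chained continuously: each
#' segment starts at the temperature where the previous one ended.
#'
#' @name temperature_protocol
#' @seealso [make_trapezoid()], [make_experimental_like()],
#'   [load_trace()], [protocol_evaluate()]
NULL

new_protocol <- function(segments, source = "analytic", trace = NULL) {
  segments$t0 <- cumsum(c(0, segments$duration))[seq_len(nrow(segments))]
  segments$t1 <- segments$t0 + segments$duration
  structure(list(segments = segments,
                 total_duration = segments$t1[nrow(segments)],
                 source = source, trace = trace),
            class = "temperature_protocol")
}

seg_row <- function(shape, duration, T0, T1, rate = NA_real_, tau = NA_real_) {
  if (duration <= 0) stop("segment durations must be > 0")
  data.frame(shape = shape, duration = duration, T0 = T0, T1 = T1,
             rate = rate, tau = tau, stringsAsFactors = FALSE)
}

#' Constant-temperature protocol
#'
#' A single hold segment, used for steady-state activity-map cells.
#'
#' @param temp_C hold temperature (deg C).
#' @param duration hold duration (s).
#' @return a `temperature_protocol`.
#' @export
make_hold <- function(temp_C, duration) {
  new_protocol(seg_row("hold", duration, temp_C, temp_C, rate = 0))
}

#' Trapezoid cooling protocol
#'
#' Hold at `T_start`, fall linearly at `-rate` to `T_min`, hold, rise
#' linearly at `+rate` back to `T_start`, hold.  This is the constant-rate
#' stimulus used for the rate and magnitude sweeps (reference
#' configuration: 24 degC held 30 s, fall to 10 degC, 30 s cold hold,
#' symmetric return, 30 s post hold).
#'
#' @param T_start warm (room) temperature (deg C).
#' @param T_min cold target temperature (deg C), < `T_start`.
#' @param rate absolute ramp rate (deg C/s), > 0.
#' @param hold_pre,hold_cold,hold_post hold durations (s).
#' @return a `temperature_protocol`.
#' @examples
#' p <- make_trapezoid(24, 10, 3)
#' p$total_duration  # 30 + 14/3 + 30 + 14/3 + 30
#' @export
make_trapezoid <- function(T_start = 24, T_min = 10, rate,
                           hold_pre = 30, hold_cold = 30, hold_post = 30) {
  if (rate <= 0) stop("ramp rate must be > 0")
  if (T_min >= T_start) stop("T_min must be below T_start")
  leg <- (T_start - T_min) / rate
  segs <- rbind(
    if (hold_pre > 0) seg_row("hold", hold_pre, T_start, T_start, 0),
    seg_row("linear", leg, T_start, T_min, -rate),
    if (hold_cold > 0) seg_row("hold", hold_cold, T_min, T_min, 0),
    seg_row("linear", leg, T_min, T_start, rate),
    if (hold_post > 0) seg_row("hold", hold_post, T_start, T_start, 0)
  )
  pr <- new_protocol(segs)
  pr$kind <- "trapezoid"
  pr
}

#' Experimental-like fast and slow cooling protocols
#'
#' Idealized versions of the two bench stimulation methods.  The fast
#' (perfusate-switch) protocol approaches the target exponentially,
#' `T(t) = T_target + (T_room - T_target) exp(-t/tau)` with
#' `tau = (T_room - T_target)/initial_rate`, so the initial slope is
#' `-initial_rate` (typically 2 to 6 degC/s); the exponential leg is
#' truncated once within 0.05 degC of the target, held 60 s, and returned
#' symmetrically.  The slow (controlled-ramp) protocol is a linear ramp at
#' -0.12 degC/s to the target, a 30 s hold, and a linear return.
#'
#' @param kind `"fast"` or `"slow"`.
#' @param T_target cold target temperature (deg C).
#' @param initial_rate initial cooling speed of the fast protocol
#'   (deg C/s); values outside 2-6 trigger a warning (recorded traces
#'   vary) but are accepted.
#' @param T_room starting temperature (deg C).
#' @param hold_pre,hold_post warm holds before/after the stimulus (s).
#' @param hold_cold duration at the target (s); defaults to 60 (fast) or
#'   30 (slow).
#' @param slow_rate ramp speed of the slow protocol (deg C/s).
#' @return a `temperature_protocol`.
#' @examples
#' fast <- make_experimental_like("fast", 10, initial_rate = 4)
#' protocol_evaluate(fast, 30)$rate  # about -4 at stimulus onset
#' @export
make_experimental_like <- function(kind = c("fast", "slow"), T_target = 10,
                                   initial_rate = 4, T_room = 24,
                                   hold_pre = 30, hold_post = 30,
                                   hold_cold = NULL, slow_rate = 0.12) {
  kind <- match.arg(kind)
  if (T_target >= T_room) stop("T_target must be below T_room")
  if (kind == "fast") {
    if (initial_rate < 2 || initial_rate > 6)
      warning("fast-protocol initial rate ", initial_rate,
              " degC/s is outside the 2-6 degC/s envelope")
    if (is.null(hold_cold)) hold_cold <- 60
    dT <- T_room - T_target
    tau <- dT / initial_rate
    leg <- tau * log(dT / 0.05)       # truncate within 0.05 degC of target
    T_end <- T_target + dT * exp(-leg / tau)
    T_back <- T_room - (T_room - T_end) * exp(-leg / tau)
    segs <- rbind(
      if (hold_pre > 0) seg_row("hold", hold_pre, T_room, T_room, 0),
      seg_row("exponential", leg, T_room, T_end, tau = tau),
      seg_row("hold", hold_cold, T_end, T_end, 0),
      seg_row("exponential", leg, T_end, T_back, tau = tau),
      if (hold_post > 0) seg_row("hold", hold_post, T_back, T_back, 0)
    )
    pr <- new_protocol(segs)
  } else {
    if (is.null(hold_cold)) hold_cold <- 30
    leg <- (T_room - T_target) / slow_rate
    segs <- rbind(
      if (hold_pre > 0) seg_row("hold", hold_pre, T_room, T_room, 0),
      seg_row("linear", leg, T_room, T_target, -slow_rate),
      seg_row("hold", hold_cold, T_target, T_target, 0),
      seg_row("linear", leg, T_target, T_room, slow_rate),
      if (hold_post > 0) seg_row("hold", hold_post, T_room, T_room, 0)
    )
    pr <- new_protocol(segs)
  }
  pr$kind <- kind
  pr
}

#' Load a recorded temperature trace
#'
#' Reads a two-column plain-text file (time in s, temperature in deg C;
#' comma, tab or whitespace separated; header row optional) and returns a
#' protocol that replays it by linear interpolation.
#'
#' @param path file path.
#' @return a `temperature_protocol` with `source = "trace"`.
#' @export
load_trace <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                  if (sep == ",") "," else "[ \t]+")[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  protocol_from_trace(df, origin = path)
}

#' @rdname load_trace
#' @param trace a two-column data frame (time s, temperature deg C).
#' @param origin label recorded in the protocol (e.g. the source file).
#' @export
protocol_from_trace <- function(trace, origin = "trace") {
  if (ncol(trace) < 2) stop("trace must have two columns (time, temperature)")
  tt <- as.numeric(trace[[1]]); tv <- as.numeric(trace[[2]])
  if (length(tt) < 2) stop("trace needs at least 2 rows, got ", length(tt))
  bad <- which(!is.finite(tt) | !is.finite(tv))
  if (length(bad)) stop("non-finite value in trace at row ", bad[1])
  nonmono <- which(diff(tt) <= 0)
  if (length(nonmono))
    stop("trace time must be strictly increasing; violation at row ",
         nonmono[1] + 1)
  if (tt[1] != 0) { tv <- c(tv[1], tv); tt <- c(0, tt) }
  structure(list(segments = NULL, total_duration = tt[length(tt)],
                 source = "trace", origin = origin,
                 trace = data.frame(time = tt, temperature = tv)),
            class = "temperature_protocol")
}

#' Evaluate a protocol
#'
#' Temperature and rate of change at time(s) `t`.  For analytic protocols
#' the rate is the exact segment derivative; for traces it is the local
#' finite-difference slope.
#'
#' @param protocol a `temperature_protocol`.
#' @param t time(s) in s, within `[0, total_duration]`.
#' @return `list(temperature = , rate = )` in deg C and deg C/s.
#' @examples
#' protocol_evaluate(make_trapezoid(24, 10, 3), 32)  # on the falling leg
#' @export
protocol_evaluate <- function(protocol, t) {
  if (any(t < -1e-9 | t > protocol$total_duration + 1e-9))
    stop("time out of protocol range [0, ", protocol$total_duration, "]")
  t <- pmin(pmax(t, 0), protocol$total_duration)
  if (protocol$source == "trace") {
    tr <- protocol$trace
    temp <- stats::approx(tr$time, tr$temperature, xout = t, rule = 2)$y
    slopes <- diff(tr$temperature) / diff(tr$time)
    idx <- pmin(pmax(findInterval(t, tr$time), 1), length(slopes))
    return(list(temperature = temp, rate = slopes[idx]))
  }
  sg <- protocol$segments
  idx <- pmin(pmax(findInterval(t, sg$t0), 1), nrow(sg))
  rel <- t - sg$t0[idx]
  temp <- numeric(length(t)); rate <- numeric(length(t))
  for (k in seq_along(t)) {
    s <- sg[idx[k], ]
    if (s$shape == "hold") {
      temp[k] <- s$T0; rate[k] <- 0
    } else if (s$shape == "linear") {
      temp[k] <- s$T0 + s$rate * rel[k]; rate[k] <- s$rate
    } else {            # exponential approach toward the asymptote
      # asymptote reconstructed from endpoints and tau
      a <- (s$T1 - s$T0 * exp(-s$duration / s$tau)) /
        (1 - exp(-s$duration / s$tau))
      temp[k] <- a + (s$T0 - a) * exp(-rel[k] / s$tau)
      rate[k] <- -(s$T0 - a) / s$tau * exp(-rel[k] / s$tau)
    }
  }
  list(temperature = temp, rate = rate)
}

# dense (time, Kelvin) sample table used as the integrator's forcing
protocol_samples <- function(protocol, dt = 0.01) {
  if (protocol$source == "trace") {
    tt <- protocol$trace$time; tv <- protocol$trace$temperature
  } else {
    sg <- protocol$segments
    tt <- unlist(lapply(seq_len(nrow(sg)), function(i) {
      s <- sg[i, ]
      if (s$shape == "exponential")
        seq(s$t0, s$t1, length.out = max(2, ceiling(s$duration / dt) + 1))
      else c(s$t0, s$t1)
    }))
    keep <- !duplicated(tt)
    tt <- tt[keep]
    tv <- protocol_evaluate(protocol, tt)$temperature
  }
  cbind(time = tt, temp_K = celsius_to_kelvin(tv))
}

protocol_start_temp <- function(protocol) {
  protocol_evaluate(protocol, 0)$temperature
}

# time at which the temperature first leaves its initial value
protocol_onset <- function(protocol, eps = 0.05) {
  if (protocol$source == "trace") {
    tr <- protocol$trace
    i <- which(abs(tr$temperature - tr$temperature[1]) > eps)
    if (!length(i)) return(0)
    return(tr$time[i[1] - 1])
  }
  sg <- protocol$segments
  i <- which(sg$shape != "hold")
  if (!length(i)) return(0)
  sg$t0[i[1]]
}

#' Write a protocol as a two-column trace file
#'
#' Samples the protocol on a regular grid and writes a CSV readable by
#' [load_trace()].
#'
#' @param protocol a `temperature_protocol`.
#' @param path output file.
#' @param rate_hz sampling rate (Hz), default 100.
#' @return `path`, invisibly.
#' @export
write_trace <- function(protocol, path, rate_hz = 100) {
  t <- seq(0, protocol$total_duration, by = 1 / rate_hz)
  df <- data.frame(time_s = t,
                   temp_C = protocol_evaluate(protocol, t)$temperature)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.temperature_protocol <- function(x, ...) {
  cat(sprintf("Temperature protocol (%s), duration %.2f s\n",
              x$source, x$total_duration))
  if (x$source == "analytic") {
    sg <- x$segments
    for (i in seq_len(nrow(sg)))
      cat(sprintf("  %8.2f-%8.2f s  %-11s %6.2f -> %6.2f degC\n",
                  sg$t0[i], sg$t1[i], sg$shape[i], sg$T0[i], sg$T1[i]))
  } else {
    cat(sprintf("  %d samples, %.2f to %.2f degC\n", nrow(x$trace),
                min(x$trace$temperature), max(x$trace$temperature)))
  }
  invisible(x)
}
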