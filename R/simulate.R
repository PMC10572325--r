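#' Integrate the model under a temperature protocol
#'
#' Drives the stiff variable-step integration (backward differentiation
#' formulas via \pkg{deSolve}, compiled right-hand side, temperature
#' supplied as a forcing function) over the full protocol duration and
#' returns the solution on a fixed dense output grid.  Default tolerances
#' are absolute 1e-9 and relative 1e-8; default output sampling is 2 kHz,
#' dense enough to resolve the millisecond-scale spikes for 0 mV-crossing
#' detection.
#'
#' @param params a [neuron_parameters()] object.
#' @param trp a [trp_parameters()] object.
#' @param protocol a `temperature_protocol` (or a single temperature in
#'   deg C, treated as a hold for `duration` seconds).
#' @param ic named initial state, e.g. from [pre_integrate()]; default
#'   [initial_state()] at the protocol's starting temperature.
#' @param duration simulated time (s); defaults to the protocol duration.
#' @param atol,rtol solver tolerances.
#' @param output_rate output grid sampling rate (Hz).
#' @param hmax maximal internal step (s); bounds how far the solver can
#'   step across protocol breakpoints.
#' @param method \pkg{deSolve} integration method, default `"bdf"`.
#' @param maxsteps maximal internal steps per output interval.
#' @return an object of class `simulation_result`: a list with `data` (a
#'   data frame of time, temperature in deg C, `Vm`, all gating variables,
#'   `Ca_i`, every current, `E_Ca`, `E_TRP` and `G_TRP_inst`), plus the
#'   inputs and solver metadata sufficient to reproduce the run.
#' @examples
#' \donttest{
#' p <- neuron_parameters()
#' tr <- trp_parameters("leak", G_LTRP = 0.28)
#' res <- run_protocol(p, tr, make_hold(10, 2))
#' }
#' @export
run_protocol <- function(params, trp, protocol, ic = NULL, duration = NULL,
                         atol = 1e-9, rtol = 1e-8, output_rate = 2000,
                         hmax = 0.1, method = "bdf", maxsteps = 10000) {
  if (!inherits(protocol, "temperature_protocol")) {
    stopifnot(is.numeric(protocol), length(protocol) == 1)
    protocol <- make_hold(protocol, if (is.null(duration)) 100 else duration)
  }
  if (is.null(duration)) duration <- protocol$total_duration
  if (duration > protocol$total_duration + 1e-9)
    stop("requested duration exceeds the protocol domain")
  if (atol <= 0 || rtol <= 0) stop("tolerances must be > 0")
  if (is.null(ic))
    ic <- initial_state(params, trp, temp_C = protocol_start_temp(protocol))
  ic <- ic[state_names()]
  if (anyNA(ic)) stop("initial state is incomplete")

  times <- seq(0, duration, by = 1 / output_rate)
  pp <- pack_parms(params, trp)
  out <- deSolve::ode(
    y = ic, times = times, func = "ciii_derivs", parms = pp,
    dllname = "coldburst", initfunc = "ciii_initmod",
    initforc = "ciii_initforc", forcings = protocol_samples(protocol),
    fcontrol = list(method = "linear", rule = 2),
    method = method, atol = atol, rtol = rtol, hmax = hmax,
    maxsteps = maxsteps, nout = 12, outnames = current_names())
  if (nrow(out) < length(times) || anyNA(out[nrow(out), ]))
    stop("integration failed near t = ", out[nrow(out), 1], " s")

  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df$temperature <- kelvin_to_celsius(df$temp_K)
  structure(list(data = df, params = params, trp = trp, protocol = protocol,
                 meta = list(atol = atol, rtol = rtol,
                             output_rate = output_rate, hmax = hmax,
                             method = method, parms = pp)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  d <- x$data
  cat(sprintf(paste0("Simulation result: %.2f s at %g Hz output ",
                     "(%d samples)\n"),
              max(d$time), x$meta$output_rate, nrow(d)))
  cat(sprintf("  Vm in [%.1f, %.1f] mV; temperature %.1f to %.1f degC; TRP mode %s\n",
              min(d$Vm), max(d$Vm), d$temperature[1],
              min(d$temperature), x$trp$mode))
  invisible(x)
}

#' Settle the model at room temperature
#'
#' Runs the model for `duration` seconds (default 100) at a constant room
#' temperature and returns the final state, which serves as the initial
#' condition for protocol runs and map sweeps.  The result samples the
#' attractor at that temperature (a fixed point for quiescent parameter
#' sets, a point on the spiking orbit otherwise).
#'
#' @inheritParams run_protocol
#' @param T_room room temperature (deg C), default 24.
#' @param duration settling time (s), default 100.
#' @return a named state vector.
#' @examples
#' \donttest{
#' st <- pre_integrate(neuron_parameters(), trp_parameters("leak"))
#' }
#' @export
pre_integrate <- function(params, trp, T_room = 24, duration = 100,
                          atol = 1e-9, rtol = 1e-8, ...) {
  if (duration <= 0) stop("duration must be > 0")
  res <- run_protocol(params, trp, make_hold(T_room, duration),
                      atol = atol, rtol = rtol, output_rate = 10, ...)
  final_state(res)
}

#' Final state of a simulation
#'
#' @param result a `simulation_result`.
#' @return named state vector at the last stored sample.
#' @export
final_state <- function(result) {
  last <- result$data[nrow(result$data), ]
  stats::setNames(as.numeric(last[state_names()]), state_names())
}

#' Simulate one activity-map cell
#'
#' Holds the level-I (leak TRP) model at a fixed `(G_LTRP, temperature)`
#' point: starting from the room-temperature pre-integrated state, the
#' model is settled for `settle` seconds and analyzed over the following
#' `analyze` seconds.  Pattern label and per-cell metrics are computed on
#' the analysis window.
#'
#' @inheritParams run_protocol
#' @param G_LTRP leak TRP conductance (nS).
#' @param temp_C cell temperature (deg C).
#' @param ic the room-temperature pre-integrated state ([pre_integrate()]).
#' @param settle settling time at the cell condition (s), default 60.
#' @param analyze analysis-window length (s), default 40.
#' @param trp optional leak-mode TRP template whose permeability settings
#'   are reused (its `G_LTRP` is overridden).
#' @return `list(result = , metrics = )`: the analysis-window
#'   `simulation_result` and a one-row data frame of metrics (pattern
#'   label, spike count, mean rate, mean frequency, spikes per burst,
#'   mean Ca2+).
#' @export
run_map_cell <- function(params, G_LTRP, temp_C, ic, settle = 60,
                         analyze = 40, trp = NULL, ...) {
  if (is.null(trp)) trp <- trp_parameters("leak")
  trp$mode <- "leak"
  trp$G_LTRP <- G_LTRP
  res <- run_protocol(params, trp, make_hold(temp_C, settle + analyze),
                      ic = ic, ...)
  win <- window_result(res, settle, settle + analyze)
  metrics <- cell_metrics(win)
  metrics$G_LTRP <- G_LTRP
  metrics$temperature <- temp_C
  list(result = win, metrics = metrics)
}

# restrict a simulation_result to a time window (keeps absolute times)
window_result <- function(result, t0, t1) {
  keep <- result$data$time >= t0 - 1e-9 & result$data$time <= t1 + 1e-9
  out <- result
  out$data <- result$data[keep, , drop = FALSE]
  out$window <- c(t0, t1)
  out
}

# metrics of a steady-state analysis window
cell_metrics <- function(win, isi_max = 0.2, min_spikes = 3) {
  train <- detect_spikes(win)
  bursts <- classify_bursts(train, isi_max = isi_max, min_spikes = min_spikes)
  lab <- classify_pattern(train, bursts, trace = win)
  dur <- diff(range(win$data$time))
  n <- length(train$spike_times)
  isi <- diff(train$spike_times)
  nb <- nrow(bursts$bursts)
  intra <- intra_burst_isis(train, bursts)
  mean_freq <- if (nb >= 1 && length(intra)) mean(1 / intra)
               else if (length(isi)) mean(1 / isi) else 0
  data.frame(
    label = lab$label,
    n_spikes = n,
    spiking_rate = n / dur,
    mean_frequency = mean_freq,
    n_bursts = nb,
    spikes_per_burst = if (nb >= 1) mean(bursts$bursts$n_spikes) else 0,
    mean_Ca = mean(win$data$Ca_i),
    stringsAsFactors = FALSE
  )
}

#' Check state invariants on every stored sample
#'
#' Verifies that all gating variables stay within [0, 1] (m_TRP within
#' [0, B]), that Ca2+ stays positive and that all samples are finite.
#'
#' @param result a `simulation_result`.
#' @param tol numerical slack for gate bounds.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_state_invariants <- function(result, tol = 1e-6) {
  d <- result$data
  gates <- c("m_Na", "h_Na", "m_K", "m_Ca", "h_Ca", "m_BK", "f_SK", "h_TRP")
  for (g in gates) {
    if (any(!is.finite(d[[g]]))) stop("non-finite ", g)
    if (any(d[[g]] < -tol | d[[g]] > 1 + tol))
      stop(g, " leaves [0,1]: range ", min(d[[g]]), " .. ", max(d[[g]]))
  }
  B <- result$trp$B
  if (any(d$m_TRP < -tol | d$m_TRP > B + tol))
    stop("m_TRP leaves [0, B]")
  if (any(!is.finite(d$Vm)) || any(!is.finite(d$Ca_i)))
    stop("non-finite Vm or Ca_i")
  if (any(d$Ca_i <= 0)) stop("Ca_i not positive")
  invisible(TRUE)
}
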