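#' Two-parameter (conductance, temperature) activity map
#'
#' Sweeps the level-I model over a grid of constant TRP leak conductances
#' and steady temperatures, simulating every cell independently (60 s
#' settle + 40 s analysis per cell) from the room-temperature
#' pre-integrated state of its conductance column, and recording the
#' activity-pattern label, mean
#' frequency (mean intra-burst frequency for bursting cells, mean 1/ISI
#' otherwise), spiking rate, mean spikes per burst and mean intracellular
#' Ca2+.  The reference grid is G_LTRP from 0 to 1 nS in 0.02 nS steps by
#' temperature from 24 down to 4 degC in 0.5 degC steps.
#'
#' @param params a [neuron_parameters()] object.
#' @param g_grid conductance grid (nS).
#' @param t_grid temperature grid (deg C).
#' @param ic optional shared initial state for every cell; by default
#'   each conductance column starts from the 100 s room-temperature
#'   pre-integration of the model with that column's own `G_LTRP`.
#' @param T_room room temperature for the shared pre-integration (deg C).
#' @param settle,analyze per-cell settle and analysis durations (s).
#' @param trp optional leak-mode TRP template (permeability settings).
#' @param ... further arguments to [run_protocol()].
#' @return an `activity_map`: list with `g_grid`, `t_grid`, `cells` (one
#'   row per cell with the metrics above) and `meta`.  Cells whose
#'   integration fails are flagged in `cells$failed` and the sweep
#'   continues.
#' @examples
#' \donttest{
#' m <- sweep_map(neuron_parameters(), g_grid = c(0, 0.3),
#'                t_grid = c(14, 10))
#' }
#' @export
sweep_map <- function(params, g_grid = seq(0, 1, by = 0.02),
                      t_grid = seq(24, 4, by = -0.5), ic = NULL,
                      T_room = 24, settle = 60, analyze = 40, trp = NULL,
                      ...) {
  if (!length(g_grid) || !length(t_grid)) stop("grids must be nonempty")
  if (is.null(trp)) trp <- trp_parameters("leak")
  shared_ic <- ic
  cells <- vector("list", length(g_grid) * length(t_grid))
  i <- 0
  failures <- character(0)
  for (g in g_grid) {
    # cells of one conductance column share the room-temperature
    # pre-integrated state of the model with that conductance
    trp_g <- trp
    trp_g$G_LTRP <- g
    ic <- if (is.null(shared_ic))
      pre_integrate(params, trp_g, T_room = T_room) else shared_ic
    for (tc in t_grid) {
    i <- i + 1
    m <- tryCatch(
      run_map_cell(params, g, tc, ic, settle = settle, analyze = analyze,
                   trp = trp, ...)$metrics,
      error = function(e) {
        data.frame(label = NA_character_, n_spikes = NA_integer_,
                   spiking_rate = NA_real_, mean_frequency = NA_real_,
                   n_bursts = NA_integer_, spikes_per_burst = NA_real_,
                   mean_Ca = NA_real_, G_LTRP = g, temperature = tc,
                   stringsAsFactors = FALSE)
      })
    m$failed <- is.na(m$label)
    if (m$failed) failures <- c(failures, sprintf("(%.3g nS, %.3g degC)", g, tc))
    cells[[i]] <- m
    }
  }
  cells <- do.call(rbind, cells)
  if (length(failures))
    warning(length(failures), " map cell(s) failed: ",
            paste(failures, collapse = ", "))
  structure(list(g_grid = g_grid, t_grid = t_grid, cells = cells,
                 meta = list(settle = settle, analyze = analyze,
                             T_room = T_room, parms = pack_parms(params, trp),
                             params = params, trp = trp)),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("Activity map: %d x %d cells (G %.3g-%.3g nS, T %.3g-%.3g degC)\n",
              length(x$g_grid), length(x$t_grid), min(x$g_grid), max(x$g_grid),
              max(x$t_grid), min(x$t_grid)))
  print(table(x$cells$label))
  invisible(x)
}

#' Threshold temperature per conductance column
#'
#' The warmest grid temperature at which the model produces spikes, as a
#' function of G_LTRP (NA for columns that are silent throughout).
#'
#' @param map an `activity_map`.
#' @return data frame with `G_LTRP` and `threshold_temperature`.
#' @export
activity_threshold <- function(map) {
  out <- lapply(split(map$cells, map$cells$G_LTRP), function(d) {
    act <- d$temperature[!is.na(d$n_spikes) & d$n_spikes > 0]
    data.frame(G_LTRP = d$G_LTRP[1],
               threshold_temperature = if (length(act)) max(act) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$G_LTRP), ]
}

#' Firing-rate-versus-temperature curve and its shape
#'
#' Computes (or extracts from a map) the mean spiking rate of the level-I
#' model at one conductance over a temperature grid and classifies the
#' curve shape: `silent` (no spikes anywhere), `peaked_then_decline`
#' (the rate falls off by more than 10% of its maximum at the cold end),
#' `saturating` (the final rate stays within 10% of the maximum over at
#' least the last quarter of the active range), or `monotonic` (still
#' rising at the cold end).  The temperature of maximal rate is reported.
#'
#' @param params a [neuron_parameters()] object.
#' @param G_LTRP the conductance (nS).
#' @param t_grid temperature grid (deg C), warm to cold.
#' @param map optional precomputed `activity_map` containing this
#'   conductance column (avoids re-simulation).
#' @param ic optional pre-integrated state.
#' @param ... further arguments to [sweep_map()].
#' @return list with `curve` (data frame: temperature, rate), `shape`,
#'   and `argmax_temperature`.
#' @export
rate_response_curve <- function(params, G_LTRP, t_grid = seq(24, 4, by = -0.5),
                                map = NULL, ic = NULL, ...) {
  if (is.null(map)) {
    map <- sweep_map(params, g_grid = G_LTRP, t_grid = t_grid, ic = ic, ...)
  }
  d <- map$cells[abs(map$cells$G_LTRP - G_LTRP) < 1e-12, ]
  if (!nrow(d)) stop("conductance ", G_LTRP, " nS not on the map grid")
  d <- d[order(-d$temperature), ]
  curve <- data.frame(temperature = d$temperature, rate = d$spiking_rate)
  r <- curve$rate
  if (all(r == 0 | is.na(r))) {
    return(list(curve = curve, shape = "silent", argmax_temperature = NA_real_))
  }
  imax <- which.max(r)
  rmax <- r[imax]
  r_end <- r[length(r)]
  active <- which(r > 0)
  shape <- if ((rmax - r_end) / rmax > 0.10) {
    "peaked_then_decline"
  } else {
    # within 10% of max at the cold end: monotonic rise or plateau?
    i90 <- active[which(r[active] >= 0.9 * rmax)][1]
    plateau_frac <- (length(r) - i90) / max(1, length(r) - active[1])
    if (plateau_frac >= 0.25) "saturating" else "monotonic"
  }
  list(curve = curve, shape = shape,
       argmax_temperature = curve$temperature[imax])
}

#' Project a level-II conductance trajectory onto an activity map
#'
#' Extracts the instantaneous TRP conductance G_TRP(t) = G_max m h and
#' temperature of a dynamic-TRP simulation as a path over the level-I
#' (G_LTRP, temperature) plane, annotates every detected spike with its
#' instantaneous frequency, and (when a map is supplied) reports which
#' map regime the nearest grid cell assigns at each output sample.
#'
#' @param result a level-II `simulation_result` (dynamic TRP mode).
#' @param map optional `activity_map` for regime lookup; its non-TRP
#'   membrane parameters must match the simulation's.
#' @param thin keep every `thin`-th sample of the path (the spike
#'   annotations are never thinned).
#' @return a `conductance_trajectory`: list with `path` (time,
#'   temperature, G_TRP_inst, regime label) and `spikes` (time,
#'   temperature, G_TRP_inst, inst_freq).
#' @export
project_trajectory <- function(result, map = NULL, thin = 10L) {
  if (result$trp$mode != "dynamic")
    stop("trajectory projection needs a dynamic (level-II) simulation")
  if (!is.null(map)) {
    if (!identical(unclass(map$meta$params), unclass(result$params)))
      stop("map and simulation use different membrane parameters; ",
           "refusing to project the trajectory")
  }
  d <- result$data
  idx <- seq(1, nrow(d), by = max(1L, as.integer(thin)))
  path <- data.frame(time = d$time[idx], temperature = d$temperature[idx],
                     G_TRP_inst = d$G_TRP_inst[idx])
  if (!is.null(map)) {
    gi <- vapply(path$G_TRP_inst, function(g)
      which.min(abs(map$g_grid - g)), 0L)
    ti <- vapply(path$temperature, function(tc)
      which.min(abs(map$t_grid - tc)), 0L)
    key <- paste(map$g_grid[gi], map$t_grid[ti])
    cellkey <- paste(map$cells$G_LTRP, map$cells$temperature)
    path$regime <- map$cells$label[match(key, cellkey)]
  }
  train <- detect_spikes(result)
  fr <- isi_frequency(train)
  n <- length(train$spike_times)
  sp <- data.frame(time = train$spike_times,
                   inst_freq = if (n) c(NA_real_, fr$freq) else numeric(0))
  at <- pmin(pmax(findInterval(sp$time, d$time), 1), nrow(d))
  sp$temperature <- d$temperature[at]
  sp$G_TRP_inst <- d$G_TRP_inst[at]
  structure(list(path = path, spikes = sp, trp = result$trp),
            class = "conductance_trajectory")
}

#' @export
print.conductance_trajectory <- function(x, ...) {
  cat(sprintf(paste0("TRP conductance trajectory: %d samples, G in ",
                     "[%.3g, %.3g] nS, %d spikes\n"),
              nrow(x$path), min(x$path$G_TRP_inst), max(x$path$G_TRP_inst),
              nrow(x$spikes)))
  if (!is.null(x$path$regime)) {
    occ <- rle(as.character(x$path$regime))
    cat("  regime sequence:", paste(occ$values, collapse = " -> "), "\n")
  }
  invisible(x)
}

# classify the activity pattern of one phase of a protocol run
phase_pattern <- function(train, t0, t1, isi_max = 0.2, contrast = 2) {
  ts <- train$spike_times
  sub <- spike_train(ts[ts >= t0 & ts <= t1], window = c(t0, t1),
                     source = train$source)
  suppressWarnings(classify_pattern(sub, isi_max = isi_max,
                                    contrast = contrast))
}

#' Sweep the rate of temperature decrease (trapezoid protocols)
#'
#' Runs the level-II model under trapezoid protocols from `T_start` to
#' `T_min` at each requested ramp rate and reports, for the falling phase
#' of each protocol: the spiking rate (spikes during the fall divided by
#' fall duration), the maximal instantaneous frequency, the number of
#' contrasted bursts and the pattern label.  The smallest rate whose fall
#' phase is labeled bursting is reported as the tonic-to-bursting
#' transition rate.
#'
#' @param params a [neuron_parameters()] object.
#' @param trp a dynamic-mode [trp_parameters()] object.
#' @param rates ramp rates (deg C/s), reference grid 0.1 to 5.5 by 0.1.
#' @param T_start,T_min protocol temperatures (deg C).
#' @param ic optional 100 s room-temperature pre-integrated state.
#' @param ... further arguments to [run_protocol()].
#' @return list with `table` (one row per rate) and
#'   `transition_rate` (deg C/s; NA if no bursting fall phase).
#' @export
rate_sweep <- function(params, trp = trp_parameters("dynamic"),
                       rates = seq(0.1, 5.5, by = 0.1), T_start = 24,
                       T_min = 10, ic = NULL, ...) {
  if (any(rates <= 0)) stop("rates must be > 0")
  if (trp$mode != "dynamic") stop("rate_sweep drives the level-II model")
  if (is.null(ic)) ic <- pre_integrate(params, trp, T_room = T_start)
  rows <- lapply(rates, function(rate) {
    pr <- make_trapezoid(T_start, T_min, rate)
    res <- run_protocol(params, trp, pr, ic = ic, ...)
    onset <- protocol_onset(pr)
    fall_end <- onset + (T_start - T_min) / rate
    train <- detect_spikes(res)
    ts <- train$spike_times
    fall <- ts[ts >= onset & ts <= fall_end]
    isi <- diff(fall)
    lab <- phase_pattern(train, onset, fall_end)
    sub <- spike_train_or_empty(fall, c(onset, fall_end))
    bs <- classify_bursts(sub)
    data.frame(rate = rate,
               fall_duration = fall_end - onset,
               n_spikes_fall = length(fall),
               spiking_rate_fall = length(fall) / (fall_end - onset),
               max_inst_freq = if (length(isi)) max(1 / isi) else 0,
               n_bursts_fall = n_contrasted_bursts(sub, bs),
               max_spikes_per_burst = if (nrow(bs$bursts))
                 max(bs$bursts$n_spikes) else 0,
               pattern_fall = lab$label,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bursting <- tab$rate[tab$pattern_fall == "bursting"]
  list(table = tab,
       transition_rate = if (length(bursting)) min(bursting) else NA_real_)
}

spike_train_or_empty <- function(ts, window) {
  spike_train(ts, window = window, source = "model")
}

#' Sweep the cold-temperature magnitude (trapezoid protocols)
#'
#' Runs the level-II model under trapezoid protocols at a fixed ramp rate
#' (reference 3 degC/s) down to each target temperature, and reports the
#' fall-phase pattern label and maximal intra-burst instantaneous
#' frequency together with the steady-state spiking rate during the cold
#' hold.
#'
#' @param params a [neuron_parameters()] object.
#' @param trp a dynamic-mode [trp_parameters()] object.
#' @param T_mins target temperatures (deg C), reference 20 down to 6 by
#'   0.5.
#' @param rate ramp rate (deg C/s).
#' @param T_start warm temperature (deg C).
#' @param hold_cold cold-hold duration (s).
#' @param ic optional pre-integrated state.
#' @param ... further arguments to [run_protocol()].
#' @return data frame with one row per target temperature.
#' @export
magnitude_sweep <- function(params, trp = trp_parameters("dynamic"),
                            T_mins = seq(20, 6, by = -0.5), rate = 3,
                            T_start = 24, hold_cold = 30, ic = NULL, ...) {
  if (any(T_mins >= T_start)) stop("target temperatures must be below T_start")
  if (trp$mode != "dynamic") stop("magnitude_sweep drives the level-II model")
  if (is.null(ic)) ic <- pre_integrate(params, trp, T_room = T_start)
  rows <- lapply(T_mins, function(tm) {
    pr <- make_trapezoid(T_start, tm, rate, hold_cold = hold_cold)
    res <- run_protocol(params, trp, pr, ic = ic, ...)
    onset <- protocol_onset(pr)
    fall_end <- onset + (T_start - tm) / rate
    hold_end <- fall_end + hold_cold
    train <- detect_spikes(res)
    ts <- train$spike_times
    fall <- ts[ts >= onset & ts <= fall_end]
    # bursts belong to the phase in which they start; a burst that starts
    # on the fall is completed across the phase boundary before being
    # judged, so warm targets that truncate the fall mid-burst are
    # classified like the rest
    bs_all <- classify_bursts(train)
    bf <- bs_all$bursts[bs_all$bursts$start >= onset &
                          bs_all$bursts$start <= fall_end, , drop = FALSE]
    intra <- if (nrow(bf))
      unlist(lapply(seq_len(nrow(bf)), function(k)
        diff(ts[bf$first[k]:bf$last[k]]))) else numeric(0)
    bs_fall <- bs_all
    bs_fall$bursts <- bf
    nq <- n_contrasted_bursts(train, bs_fall)
    lab <- if (nq >= 1) "bursting"
           else phase_pattern(train, onset, fall_end)$label
    data.frame(T_min = tm,
               pattern_fall = lab,
               max_intraburst_freq = if (length(intra)) max(1 / intra) else NA_real_,
               steady_rate = sum(ts > fall_end & ts <= hold_end) / hold_cold,
               n_spikes_fall = length(fall),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phenotype census over a table of TRP parameter sets
#'
#' Runs the full level-II model once per row of a TRP parameter table
#' under a common temperature protocol and classifies each response:
#' `non_responsive` (no spikes within the first 30 s after stimulus
#' onset), otherwise the pattern label of the stimulus window
#' (`bursting`, `tonic`, `plateau`, `depol_block`; period-2 responses
#' are counted as tonic).  Rows that fail to integrate are excluded from
#' the denominators with a warning.
#'
#' @param params a [neuron_parameters()] object.
#' @param trp_table data frame with columns among `T_h_K`, `B`, `A`,
#'   `N`, `Ca_h`, `tau_hTRP`, `tau_mTRP`, `G_TRP_max` (missing columns
#'   fall back to the defaults of [trp_parameters()]).
#' @param protocol the common `temperature_protocol`.
#' @param trp_defaults template TRP parameter set supplying unlisted
#'   fields.
#' @param window analysis window after stimulus onset (s); defaults to
#'   the remainder of the protocol.
#' @param ... further arguments to [run_protocol()].
#' @return list with `per_row` (the table plus a `label` column),
#'   `counts` and `fractions`.
#' @export
phenotype_census <- function(params, trp_table, protocol,
                             trp_defaults = trp_parameters("dynamic"),
                             window = NULL, ...) {
  if (!nrow(trp_table)) stop("TRP parameter table is empty")
  onset <- protocol_onset(protocol)
  t_end <- if (is.null(window)) protocol$total_duration
           else min(protocol$total_duration, onset + window)
  labels <- character(nrow(trp_table))
  for (i in seq_len(nrow(trp_table))) {
    trp <- trp_defaults
    for (nm in intersect(names(trp_table),
                         c("G_TRP_max", "A", "B", "N", "Ca_h",
                           "tau_mTRP", "tau_hTRP"))) {
      v <- trp_table[[nm]][i]
      if (!is.na(v)) trp[[nm]] <- v
    }
    if ("T_h_K" %in% names(trp_table) && !is.na(trp_table$T_h_K[i]))
      trp$T_h <- trp_table$T_h_K[i]
    labels[i] <- tryCatch({
      ic <- pre_integrate(params, trp,
                          T_room = protocol_start_temp(protocol))
      res <- run_protocol(params, trp, protocol, ic = ic, ...)
      train <- detect_spikes(res)
      ts <- train$spike_times
      if (!any(ts >= onset & ts <= onset + 30)) "non_responsive"
      else {
        sub <- spike_train_or_empty(ts[ts >= onset & ts <= t_end],
                                    c(onset, t_end))
        lab <- suppressWarnings(
          classify_pattern(sub, trace = window_result(res, onset, t_end)))$label
        if (lab == "period2") "tonic" else lab
      }
    }, error = function(e) NA_character_)
  }
  failed <- is.na(labels)
  if (any(failed))
    warning(sum(failed), " row(s) failed to integrate and were excluded")
  lv <- c("bursting", "tonic", "plateau", "depol_block", "non_responsive")
  counts <- table(factor(labels[!failed], levels = lv))
  per_row <- cbind(trp_table, label = labels, stringsAsFactors = FALSE)
  list(per_row = per_row, counts = counts,
       fractions = counts / max(1, sum(counts)))
}

#' Serialize an activity map
#'
#' Writes one CSV per metric (rows = conductance grid, columns =
#' temperature grid, with the grid values as header row and first
#' column) plus a JSON sidecar with the sweep metadata.
#'
#' @param map an `activity_map`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_activity_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- function(value) {
    m <- matrix(map$cells[[value]],
                nrow = length(map$t_grid), ncol = length(map$g_grid))
    df <- cbind(data.frame(G_LTRP = map$g_grid), as.data.frame(t(m)))
    names(df)[-1] <- sprintf("T_%g", map$t_grid)
    df
  }
  for (v in c("label", "mean_frequency", "spiking_rate", "spikes_per_burst",
              "mean_Ca"))
    utils::write.csv(wide(v), file.path(dir, paste0(v, ".csv")),
                     row.names = FALSE)
  meta <- map$meta[c("settle", "analyze", "T_room")]
  meta$g_grid <- map$g_grid
  meta$t_grid <- map$t_grid
  jsonlite::write_json(meta, file.path(dir, "map_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
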