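#' Membrane parameters of the CIII neuron model
#'
#' Returns the full parameter set of the single-compartment
#' Hodgkin-Huxley-type model of a *Drosophila* larva Class III (CIII)
#' cold-sensing neuron: maximal conductances, Boltzmann gating constants,
#' Hill constants of the Ca2+-gated K+ currents, fixed gating time
#' constants, Ca2+ handling and the physical constants used by the Nernst
#' equation.  Units are mV, s, nS, pA, nF, nM, pL and Kelvin throughout;
#' degrees Celsius appear only at user-facing interfaces.
#'
#' The defaults are the published reference set for this neuron:
#' G_Na = 80 nS, G_K = 140 nS, G_Ca = 3.5 nS, G_BK = 6 nS, G_SK = 0.31 nS,
#' G_L = 0.25 nS, Cm = 0.01 nF, and so on.  Conductances are scaled with
#' temperature by rho(T) = rho_base^((T - T0)/10) and gating kinetics by
#' phi(T) = phi_base^((T - T0)/10), with T0 = 298.15 K.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   `neuron_parameters(G_Ca = 0)`.
#' @param tau_convention how the cosh arguments of the voltage-dependent
#'   time constants tau_hNa and tau_mK are centered: `"literal"` uses
#'   Vm + Vhalf with the signed half-activation values, `"centered"` uses
#'   Vm - Vhalf, and `"magnitude"` uses Vm + |Vhalf| (centering both time
#'   constants at hyperpolarized voltages).  See the package vignette for
#'   why `"magnitude"` is the default.
#' @param tau_profile shape of the tau_hNa/tau_mK voltage dependence:
#'   `"sech"` (default) reads the published formulas as bell curves,
#'   `(a/cosh(arg) + 0.75)/1000` -- gating is fastest away from the
#'   center voltage, as in standard conductance-based models -- while
#'   `"cosh"` takes the typeset text at face value,
#'   `(a cosh(arg) + 0.75)/1000`, which makes Na+ inactivation slowest
#'   during spikes and leaves the model nearly inert (retained for
#'   auditing).  The vignette documents the evidence for the default.
#' @return an object of class `neuron_parameters` (a validated named list).
#' @examples
#' p <- neuron_parameters()
#' p$G_Na
#' neuron_parameters(G_Ca = 0)$G_Ca
#' @export
neuron_parameters <- function(..., tau_convention = c("magnitude", "literal", "centered"),
                              tau_profile = c("sech", "cosh")) {
  tau_convention <- match.arg(tau_convention)
  tau_profile <- match.arg(tau_profile)
  p <- list(
    Cm = 0.01,
    G_Na = 80, G_K = 140, G_Ca = 3.5, G_BK = 6, G_SK = 0.31, G_L = 0.25,
    E_Na = 65, E_K = -75, E_L = -75,
    Vm_Na = -24.7, Km_Na = 3.4, Vh_Na = -41.2, Kh_Na = 4.2,
    Vm_K = -12, Km_K = 7,
    Vm_Ca = -23, Km_Ca = 6.5, Vh_Ca = -59, Kh_Ca = 12,
    Vm_BK = -28.3, Km_BK = 30,
    Ca_BK = 1700, n_BK = 3, Ca_SK = 800, n_SK = 3,
    tau_mNa = 0.0001, tau_mCa = 0.0035, tau_hCa = 0.095, tau_mSK = 0.04,
    F = 96485.35e-9, R = 8.31e-9, z = 2, Vol = 0.2,
    k_Ca = 403, Ca_min = 50, Ca_e = 2e6,
    T0 = 298.15, rho_base = 1.3, phi_base = 3,
    tau_convention = tau_convention, tau_profile = tau_profile
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "neuron_parameters"
  validate_neuron_parameters(p)
  p
}

validate_neuron_parameters <- function(p) {
  gs <- c("G_Na", "G_K", "G_Ca", "G_BK", "G_SK", "G_L")
  if (any(unlist(p[gs]) < 0)) stop("conductances must be >= 0")
  for (nm in c("Cm", "Vol", "F", "R"))
    if (p[[nm]] <= 0) stop(nm, " must be > 0")
  for (nm in c("Km_Na", "Kh_Na", "Km_K", "Km_Ca", "Kh_Ca", "Km_BK"))
    if (p[[nm]] == 0) stop(nm, " must be nonzero")
  if (p$n_BK < 1 || p$n_SK < 1) stop("Hill coefficients n_BK, n_SK must be >= 1")
  if (!(p$Ca_e > p$Ca_min && p$Ca_min > 0)) stop("need Ca_e > Ca_min > 0")
  if (p$T0 <= 0 || p$rho_base <= 0 || p$phi_base <= 0)
    stop("T0, rho_base and phi_base must be > 0")
  invisible(p)
}

#' @export
print.neuron_parameters <- function(x, ...) {
  cat("CIII neuron membrane parameters\n")
  cat(sprintf("  conductances (nS): Na %.4g  K %.4g  Ca %.4g  BK %.4g  SK %.4g  L %.4g\n",
              x$G_Na, x$G_K, x$G_Ca, x$G_BK, x$G_SK, x$G_L))
  cat(sprintf("  Cm %.4g nF, T0 %.5g K, rho base %.3g, phi base %.3g\n",
              x$Cm, x$T0, x$rho_base, x$phi_base))
  cat(sprintf("  tau convention: %s\n", x$tau_convention))
  invisible(x)
}

#' TRP current parameters
#'
#' Parameters of the lumped thermoTRP current in either of its two modes:
#' `"leak"` (level-I model; constant conductance `G_LTRP`) or `"dynamic"`
#' (level-II model; maximal conductance `G_TRP_max` gated by a
#' temperature-dependent activation `m_TRP` and a Ca2+-dependent
#' inactivation `h_TRP`).
#'
#' The dynamic-mode defaults are the published reference set:
#' G_TRP_max = 1.2 nS, T_h = 290.15 K, A = 1 1/K, N = 2, Ca_h = 700 nM,
#' tau_hTRP = 10 s, tau_mTRP = 0.002 s, B = 1.
#'
#' @param mode `"leak"` or `"dynamic"`.
#' @param G_LTRP leak-mode conductance (nS).
#' @param G_TRP_max dynamic-mode maximal conductance (nS).
#' @param A activation steepness (1/K).
#' @param B activation scaling factor in (0, 1].
#' @param T_h half-activation temperature (K).
#' @param N Hill coefficient of Ca2+-dependent inactivation (>= 1).
#' @param Ca_h half-inactivation Ca2+ concentration (nM).
#' @param tau_mTRP,tau_hTRP gate time constants (s); not phi(T)-scaled.
#' @param P_K,P_Ca relative permeabilities of the TRP conductance.
#' @param E_K_fix,E_Na_fix,E_Ca_star fixed reversal potentials (mV) used to
#'   calibrate the Na+ permeability so the TRP reversal sits near 0 mV.
#' @param activation_orientation `"cold"` (default: the channel opens on
#'   cooling, m_inf = B/(1 + exp(A (T - T_h)))) or `"warm"` (the literal
#'   printed Boltzmann, which opens on warming; retained for auditing).
#' @param etrp_mode `"dynamic_ECa"` (default: the TRP reversal tracks the
#'   live Nernst Ca2+ reversal) or `"literal_constant"` (fixed E_Ca_star,
#'   which makes E_TRP identically 0 mV for the default permeabilities).
#' @return an object of class `trp_parameters`.
#' @examples
#' trp_parameters("leak", G_LTRP = 0.28)
#' trp_parameters("dynamic")
#' @export
trp_parameters <- function(mode = c("dynamic", "leak"),
                           G_LTRP = 0, G_TRP_max = 1.2,
                           A = 1, B = 1, T_h = 290.15, N = 2, Ca_h = 700,
                           tau_mTRP = 0.002, tau_hTRP = 10,
                           P_K = 1, P_Ca = 0.4,
                           E_K_fix = -75, E_Na_fix = 65, E_Ca_star = 120,
                           activation_orientation = c("cold", "warm"),
                           etrp_mode = c("dynamic_ECa", "literal_constant")) {
  mode <- match.arg(mode)
  trp <- list(
    mode = mode, G_LTRP = G_LTRP, G_TRP_max = G_TRP_max,
    A = A, B = B, T_h = T_h, N = N, Ca_h = Ca_h,
    tau_mTRP = tau_mTRP, tau_hTRP = tau_hTRP,
    P_K = P_K, P_Ca = P_Ca,
    E_K_fix = E_K_fix, E_Na_fix = E_Na_fix, E_Ca_star = E_Ca_star,
    activation_orientation = match.arg(activation_orientation),
    etrp_mode = match.arg(etrp_mode)
  )
  if (trp$G_LTRP < 0 || trp$G_TRP_max < 0) stop("TRP conductances must be >= 0")
  if (trp$A <= 0) stop("activation steepness A must be > 0")
  if (trp$B <= 0 || trp$B > 1) stop("activation scaling B must lie in (0, 1]")
  if (trp$N < 1) stop("inactivation Hill coefficient N must be >= 1")
  if (trp$Ca_h <= 0) stop("Ca_h must be > 0")
  if (trp$tau_mTRP <= 0 || trp$tau_hTRP <= 0) stop("TRP time constants must be > 0")
  if (trp$P_K <= 0 || trp$P_Ca <= 0) stop("permeabilities P_K, P_Ca must be > 0")
  class(trp) <- "trp_parameters"
  trp
}

#' @export
print.trp_parameters <- function(x, ...) {
  if (x$mode == "leak") {
    cat(sprintf("TRP leak current (level I): G_LTRP = %.4g nS\n", x$G_LTRP))
  } else {
    cat(sprintf(paste0("Dynamic TRP current (level II): G_TRP_max = %.4g nS, ",
                       "T_h = %.5g K, A = %.3g 1/K, B = %.3g\n"),
                x$G_TRP_max, x$T_h, x$A, x$B))
    cat(sprintf("  inactivation: N = %.3g, Ca_h = %.4g nM; tau_m = %.4g s, tau_h = %.4g s\n",
                x$N, x$Ca_h, x$tau_mTRP, x$tau_hTRP))
  }
  cat(sprintf("  orientation %s, E_TRP mode %s\n",
              x$activation_orientation, x$etrp_mode))
  invisible(x)
}

#' Read and write flat key-value parameter configuration files
#'
#' Parameter sets are stored as plain-text `key = value` lines (one per
#' parameter, `#` comments allowed).  Membrane parameters use their field
#' names (`G_Na`, `Vm_Na`, ...) and TRP parameters are prefixed with
#' `trp.` (`trp.mode`, `trp.G_TRP_max`, ...).  The shipped default set is
#' available via `system.file("extdata", "default_params.cfg",
#' package = "coldburst")`.
#'
#' @param path file path.
#' @return `read_params_config` returns `list(params =, trp =)`;
#'   `write_params_config` returns `path` invisibly.
#' @examples
#' cfg <- system.file("extdata", "default_params.cfg", package = "coldburst")
#' ps <- read_params_config(cfg)
#' ps$params$G_Na
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  is_trp <- startsWith(keys, "trp.")
  conv <- function(k, v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  }
  mp <- stats::setNames(lapply(seq_along(keys), function(i) conv(keys[i], vals[i])), keys)
  params <- do.call(neuron_parameters, mp[!is_trp])
  targs <- mp[is_trp]
  names(targs) <- sub("^trp\\.", "", names(targs))
  trp <- do.call(trp_parameters, targs)
  list(params = params, trp = trp)
}

#' @rdname read_params_config
#' @param params a `neuron_parameters` object.
#' @param trp a `trp_parameters` object.
#' @export
write_params_config <- function(params, trp, path) {
  fmt <- function(v) {
    if (is.character(v)) v else format(v, digits = 15)
  }
  mp <- unclass(params)
  tp <- unclass(trp)
  lines <- c(
    "# CIII neuron model parameters (mV, s, nS, pA, nF, nM, pL, K)",
    paste(names(mp), "=", vapply(mp, fmt, "")),
    "# TRP current",
    paste0("trp.", names(tp), " = ", vapply(tp, fmt, ""))
  )
  writeLines(lines, path)
  invisible(path)
}
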