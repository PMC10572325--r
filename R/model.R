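#' @useDynLib coldburst, .registration = TRUE
#' @importFrom stats approx median setNames runif uniroot
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# canonical state ordering, shared with src/ciii_model.c
state_names <- function() {
  c("Vm", "m_Na", "h_Na", "m_K", "m_Ca", "h_Ca", "m_BK", "f_SK",
    "Ca_i", "m_TRP", "h_TRP")
}

current_names <- function() {
  c("I_Na", "I_K", "I_Ca", "I_BK", "I_SK", "I_L", "I_TRP", "I_TRPCa",
    "E_Ca", "E_TRP", "G_TRP_inst", "temp_K")
}

# flatten parameters into the fixed-order double vector consumed by the
# compiled RHS; order must match the #define block in src/ciii_model.c
pack_parms <- function(params, trp) {
  tau_conv <- match(params$tau_convention, c("literal", "centered", "magnitude")) - 1
  c(params$Cm,
    params$G_Na, params$G_K, params$G_Ca, params$G_BK, params$G_SK, params$G_L,
    params$E_Na, params$E_K, params$E_L,
    params$Vm_Na, params$Km_Na, params$Vh_Na, params$Kh_Na,
    params$Vm_K, params$Km_K,
    params$Vm_Ca, params$Km_Ca, params$Vh_Ca, params$Kh_Ca,
    params$Vm_BK, params$Km_BK,
    params$Ca_BK, params$n_BK, params$Ca_SK, params$n_SK,
    params$tau_mNa, params$tau_mCa, params$tau_hCa, params$tau_mSK,
    params$F, params$R, params$z, params$Vol,
    params$k_Ca, params$Ca_min, params$Ca_e,
    params$T0, params$rho_base, params$phi_base,
    tau_conv,
    if (trp$mode == "leak") 0 else 1,
    trp$G_LTRP, trp$G_TRP_max, trp$A, trp$B, trp$T_h, trp$N, trp$Ca_h,
    trp$tau_mTRP, trp$tau_hTRP,
    trp$P_K, trp$P_Ca, sodium_permeability(trp),
    trp$E_K_fix, trp$E_Na_fix, trp$E_Ca_star,
    if (trp$activation_orientation == "cold") 0 else 1,
    if (trp$etrp_mode == "dynamic_ECa") 0 else 1,
    if (params$tau_profile == "sech") 0 else 1)
}

#' Build a model state vector
#'
#' Assembles the 11-element model state (membrane potential, gating
#' variables, intracellular Ca2+ and the two TRP gates) with every gate at
#' its steady-state value for the given voltage, Ca2+ and temperature.
#' In leak TRP mode the TRP gates are carried but inert.
#'
#' @param params a [neuron_parameters()] object.
#' @param trp a [trp_parameters()] object.
#' @param vm initial membrane potential (mV), default -60.
#' @param ca_i initial intracellular Ca2+ (nM), default the resting floor
#'   `Ca_min`.
#' @param temp_C temperature (deg C) used for the TRP activation steady
#'   state, default 24.
#' @return named numeric state vector.
#' @examples
#' initial_state(neuron_parameters(), trp_parameters("leak"))
#' @export
initial_state <- function(params, trp, vm = -60, ca_i = params$Ca_min,
                          temp_C = 24) {
  ss <- trp_steady_states(celsius_to_kelvin(temp_C), ca_i, trp)
  st <- c(
    Vm = vm,
    m_Na = boltzmann_gate(vm, params$Vm_Na, params$Km_Na, "activation"),
    h_Na = boltzmann_gate(vm, params$Vh_Na, params$Kh_Na, "inactivation"),
    m_K = boltzmann_gate(vm, params$Vm_K, params$Km_K, "activation"),
    m_Ca = boltzmann_gate(vm, params$Vm_Ca, params$Km_Ca, "activation"),
    h_Ca = boltzmann_gate(vm, params$Vh_Ca, params$Kh_Ca, "inactivation"),
    m_BK = boltzmann_gate(vm, params$Vm_BK, params$Km_BK, "activation"),
    f_SK = hill_gate(ca_i, params$Ca_SK, params$n_SK),
    Ca_i = ca_i,
    m_TRP = if (trp$mode == "dynamic") ss$m else 0,
    h_TRP = if (trp$mode == "dynamic") ss$h else 0
  )
  st
}

#' Celsius/Kelvin conversion
#'
#' The model works in Kelvin internally; protocols and user interfaces use
#' degrees Celsius.
#'
#' @param temp_C,temp_K temperatures.
#' @return converted temperature.
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_K) temp_K - 273.15

#' Instantaneous membrane currents
#'
#' Evaluates every ionic current of the model at a given state and
#' temperature: `I_Na = rho(T) G_Na m_Na^3 h_Na (Vm - E_Na)`,
#' `I_K = rho(T) G_K m_K^4 (Vm - E_K)`,
#' `I_Ca = rho(T) G_Ca m_Ca h_Ca (Vm - E_Ca)`,
#' `I_BK = rho(T) G_BK f_CaBK m_BK^4 (Vm - E_K)`,
#' `I_SK = rho(T) G_SK f_SK (Vm - E_K)`, `I_L = rho(T) G_L (Vm - E_L)`,
#' plus the TRP currents from [trp_currents()] (which are not
#' rho-scaled).  The BK Ca2+ factor f_CaBK is an instantaneous function of
#' Ca_i.  E_Ca is the live Nernst reversal.
#'
#' @param state a model state vector.
#' @param params a [neuron_parameters()] object.
#' @param trp a [trp_parameters()] object.
#' @param temp_K temperature (K).
#' @return named numeric vector of currents (pA) plus `E_Ca`, `E_TRP`
#'   (mV) and `G_TRP_inst` (nS).
#' @examples
#' p <- neuron_parameters(); tr <- trp_parameters("leak", G_LTRP = 0.5)
#' membrane_currents(initial_state(p, tr), p, tr, 297.15)
#' @export
membrane_currents <- function(state, params, trp, temp_K) {
  if (temp_K <= 0) stop("temperature must be > 0 K")
  rho <- temperature_scaling(temp_K, params$T0, params$rho_base)
  vm <- state[["Vm"]]
  ca <- state[["Ca_i"]]
  eca <- nernst_calcium(ca, params$Ca_e, temp_K, params)
  f_cabk <- hill_gate(ca, params$Ca_BK, params$n_BK)
  tc <- trp_currents(state, trp, eca)
  c(I_Na = rho * params$G_Na * state[["m_Na"]]^3 * state[["h_Na"]] * (vm - params$E_Na),
    I_K = rho * params$G_K * state[["m_K"]]^4 * (vm - params$E_K),
    I_Ca = rho * params$G_Ca * state[["m_Ca"]] * state[["h_Ca"]] * (vm - eca),
    I_BK = rho * params$G_BK * f_cabk * state[["m_BK"]]^4 * (vm - params$E_K),
    I_SK = rho * params$G_SK * state[["f_SK"]] * (vm - params$E_K),
    I_L = rho * params$G_L * (vm - params$E_L),
    I_TRP = tc$I_TRP, I_TRPCa = tc$I_TRPCa,
    E_Ca = eca, E_TRP = tc$E_TRP, G_TRP_inst = tc$g)
}

#' Time derivatives of the model state
#'
#' The full right-hand side of the model ODE system, in plain R (the
#' integrator uses an equivalent compiled version; the two are checked
#' against each other in the test suite).  Voltage obeys
#' `dVm/dt = -(I_Na + I_K + I_Ca + I_BK + I_SK + I_L + I_TRP)/Cm`
#' (mV/s with currents in pA and Cm in nF); each voltage- or Ca2+-gated
#' variable relaxes to its steady state at rate `phi(T)/tau`; intracellular
#' Ca2+ obeys
#' `dCa_i/dt = -(I_Ca + I_TRPCa)/(F z Vol) - k_Ca (Ca_i - Ca_min)` (nM/s).
#' The TRP gates (dynamic mode) relax without the phi(T) factor.
#'
#' @param t time (s).
#' @param state named model state vector.
#' @param params a [neuron_parameters()] object.
#' @param trp a [trp_parameters()] object.
#' @param protocol a [temperature_protocol] object, or a single fixed
#'   temperature in deg C.
#' @return named vector of time derivatives, same order as the state.
#' @examples
#' p <- neuron_parameters(); tr <- trp_parameters("leak")
#' st <- initial_state(p, tr)
#' state_derivatives(0, st, p, tr, 24)
#' @export
state_derivatives <- function(t, state, params, trp, protocol) {
  temp_C <- if (inherits(protocol, "temperature_protocol"))
    protocol_evaluate(protocol, t)$temperature else protocol
  temp_K <- celsius_to_kelvin(temp_C)
  phi <- temperature_scaling(temp_K, params$T0, params$phi_base)
  cur <- membrane_currents(state, params, trp, temp_K)
  vm <- state[["Vm"]]
  ca <- state[["Ca_i"]]

  relax <- function(y, yinf, tau) phi * (yinf - y) / tau
  d <- c(
    Vm = -(cur[["I_Na"]] + cur[["I_K"]] + cur[["I_Ca"]] + cur[["I_BK"]] +
             cur[["I_SK"]] + cur[["I_L"]] + cur[["I_TRP"]]) / params$Cm,
    m_Na = relax(state[["m_Na"]],
                 boltzmann_gate(vm, params$Vm_Na, params$Km_Na, "activation"),
                 params$tau_mNa),
    h_Na = relax(state[["h_Na"]],
                 boltzmann_gate(vm, params$Vh_Na, params$Kh_Na, "inactivation"),
                 voltage_dependent_tau(vm, "hNa", params)),
    m_K = relax(state[["m_K"]],
                boltzmann_gate(vm, params$Vm_K, params$Km_K, "activation"),
                voltage_dependent_tau(vm, "mK", params)),
    m_Ca = relax(state[["m_Ca"]],
                 boltzmann_gate(vm, params$Vm_Ca, params$Km_Ca, "activation"),
                 params$tau_mCa),
    h_Ca = relax(state[["h_Ca"]],
                 boltzmann_gate(vm, params$Vh_Ca, params$Kh_Ca, "inactivation"),
                 params$tau_hCa),
    m_BK = relax(state[["m_BK"]],
                 boltzmann_gate(vm, params$Vm_BK, params$Km_BK, "activation"),
                 voltage_dependent_tau(vm, "mBK", params)),
    f_SK = relax(state[["f_SK"]],
                 hill_gate(ca, params$Ca_SK, params$n_SK),
                 params$tau_mSK),
    Ca_i = -(cur[["I_Ca"]] + cur[["I_TRPCa"]]) /
      (params$F * params$z * params$Vol) - params$k_Ca * (ca - params$Ca_min),
    m_TRP = 0, h_TRP = 0
  )
  if (trp$mode == "dynamic") {
    ss <- trp_steady_states(temp_K, ca, trp)
    d[["m_TRP"]] <- (ss$m - state[["m_TRP"]]) / trp$tau_mTRP
    d[["h_TRP"]] <- (ss$h - state[["h_TRP"]]) / trp$tau_hTRP
  }
  d
}
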