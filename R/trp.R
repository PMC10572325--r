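#' Calibrated Na+ permeability of the TRP conductance
#'
#' The TRP conductance is nonspecific (K+, Na+, Ca2+).  Its relative Na+
#' permeability is chosen so that, at the fixed calibration reversal
#' potentials, the TRP reversal potential is exactly zero:
#' `P_Na = -(P_K E_K + P_Ca E_Ca*)/E_Na`.
#'
#' @param trp a [trp_parameters()] object.
#' @return the dimensionless relative Na+ permeability (27/65 for the
#'   default constants).
#' @examples
#' sodium_permeability(trp_parameters())  # 0.4153846
#' @export
sodium_permeability <- function(trp) {
  if (trp$E_Na_fix == 0) stop("E_Na_fix must be nonzero")
  -(trp$P_K * trp$E_K_fix + trp$P_Ca * trp$E_Ca_star) / trp$E_Na_fix
}

#' TRP reversal potential
#'
#' Permeability-weighted reversal
#' `E_TRP = (P_K E_K + P_Na E_Na + P_Ca E_Ca) / (P_K + P_Na + P_Ca)`.
#' In `etrp_mode = "dynamic_ECa"` (default) the Ca2+ term uses the live
#' Nernst reversal `e_ca_dyn`, so E_TRP tracks intracellular Ca2+; in
#' `"literal_constant"` mode the fixed calibration value `E_Ca_star` is
#' substituted, which makes E_TRP identically 0 mV for the default
#' constants.
#'
#' @param trp a [trp_parameters()] object.
#' @param e_ca_dyn current Nernst Ca2+ reversal potential (mV); may be a
#'   vector.  Ignored in `"literal_constant"` mode.
#' @return reversal potential (mV).
#' @examples
#' trp_reversal(trp_parameters(etrp_mode = "literal_constant"), 130)  # 0
#' @export
trp_reversal <- function(trp, e_ca_dyn) {
  p_na <- sodium_permeability(trp)
  eca <- if (trp$etrp_mode == "literal_constant") trp$E_Ca_star else e_ca_dyn
  (trp$P_K * trp$E_K_fix + p_na * trp$E_Na_fix + trp$P_Ca * eca) /
    (trp$P_K + p_na + trp$P_Ca)
}

#' Steady states of the dynamic TRP gates
#'
#' Temperature-dependent activation and Ca2+-dependent inactivation:
#' under the default cold orientation
#' `m_inf(T) = B/(1 + exp(A (T - T_h)))`, which increases on cooling and
#' equals B/2 at `T = T_h`; the `"warm"` orientation flips the exponent
#' sign (the literal printed Boltzmann).  Inactivation
#' `h_inf(Ca) = 1 - Ca^N/(Ca_h^N + Ca^N)`, decreasing in Ca with
#' half-point at `Ca_h`.
#'
#' @param temp temperature (K); may be a vector.
#' @param ca_i intracellular Ca2+ (nM), > 0; may be a vector.
#' @param trp a [trp_parameters()] object.
#' @return `list(m = , h = )` with `m` in (0, B) and `h` in (0, 1).
#' @examples
#' trp_steady_states(290.15, 700, trp_parameters())  # m = B/2, h = 0.5
#' @export
trp_steady_states <- function(temp, ca_i, trp) {
  if (any(temp <= 0)) stop("temperature must be > 0 K")
  if (any(ca_i <= 0)) stop("Ca2+ concentration must be > 0")
  s <- if (trp$activation_orientation == "cold") 1 else -1
  m <- trp$B / (1 + exp(s * trp$A * (temp - trp$T_h)))
  h <- 1 / (1 + (ca_i / trp$Ca_h)^trp$N)
  list(m = m, h = h)
}

#' Instantaneous TRP currents
#'
#' Total TRP current and its Ca2+ component:
#' `I_TRP = g (Vm - E_TRP)` and
#' `I_TRPCa = g P_Ca/(P_K + P_Na + P_Ca) (Vm - E_Ca)`, where `g` is
#' `G_LTRP` in leak mode or `G_TRP_max m_TRP h_TRP` in dynamic mode.
#' `I_TRPCa` always uses the dynamic Nernst Ca2+ reversal; it feeds the
#' Ca2+ balance and is not added separately to the voltage equation.
#' Neither current carries the rho(T) conductance scaling.
#'
#' @param state a model state vector (see [initial_state()]).
#' @param trp a [trp_parameters()] object.
#' @param e_ca_dyn the current Nernst Ca2+ reversal (mV).
#' @return `list(I_TRP = , I_TRPCa = , g = , E_TRP = )` in pA / nS / mV.
#' @export
trp_currents <- function(state, trp, e_ca_dyn) {
  g <- instantaneous_conductance(state, trp)
  etrp <- trp_reversal(trp, e_ca_dyn)
  psum <- trp$P_K + sodium_permeability(trp) + trp$P_Ca
  vm <- state[["Vm"]]
  list(I_TRP = g * (vm - etrp),
       I_TRPCa = g * (trp$P_Ca / psum) * (vm - e_ca_dyn),
       g = g, E_TRP = etrp)
}

#' Instantaneous TRP conductance
#'
#' `G_LTRP` in leak mode; `G_TRP_max m_TRP h_TRP` in dynamic mode.  This
#' is the quantity whose trajectory is projected onto the two-parameter
#' activity map of the level-I model.
#'
#' @param state a model state vector with `m_TRP`/`h_TRP` entries (any
#'   values in leak mode).
#' @param trp a [trp_parameters()] object.
#' @return conductance in nS, within `[0, G_TRP_max * B]` in dynamic mode.
#' @export
instantaneous_conductance <- function(state, trp) {
  if (trp$mode == "leak") return(trp$G_LTRP)
  if (!all(c("m_TRP", "h_TRP") %in% names(state)))
    stop("dynamic TRP mode requires m_TRP and h_TRP in the state")
  trp$G_TRP_max * state[["m_TRP"]] * state[["h_TRP"]]
}
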