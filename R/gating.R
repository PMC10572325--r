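#' Temperature scaling factor for conductances and kinetics
#'
#' Q10-style scaling `base^((T - T0)/10)`.  With `base = 1.3` this is the
#' conductance scaling rho(T); with `base = 3` the gating-kinetics scaling
#' phi(T).  Both equal 1 at the reference temperature `T0`.
#'
#' @param temp temperature (K); may be a vector.
#' @param T0 reference temperature (K), default 298.15.
#' @param base scaling base per 10 K, > 0.
#' @return dimensionless scaling factor(s).
#' @examples
#' temperature_scaling(308.15, base = 1.3)  # 1.3
#' temperature_scaling(288.15, base = 3)    # 1/3
#' @export
temperature_scaling <- function(temp, T0 = 298.15, base) {
  if (any(temp <= 0)) stop("temperature must be > 0 K")
  if (base <= 0) stop("scaling base must be > 0")
  base^((temp - T0) / 10)
}

#' Boltzmann steady-state gate
#'
#' Voltage-dependent steady state of an activation or inactivation gate:
#' activation `1/(1 + exp(-(Vm - Vhalf)/K))`, inactivation
#' `1/(1 + exp((Vm - Vhalf)/K))`.  Equals 0.5 at `Vm = Vhalf`.
#'
#' @param vm membrane potential (mV); may be a vector.
#' @param vhalf half-activation/inactivation voltage (mV).
#' @param k slope factor (mV), nonzero.
#' @param kind `"activation"` or `"inactivation"`.
#' @return gate value in (0, 1).
#' @examples
#' boltzmann_gate(-24.7, -24.7, 3.4, "activation")  # 0.5
#' @export
boltzmann_gate <- function(vm, vhalf, k, kind = c("activation", "inactivation")) {
  kind <- match.arg(kind)
  if (k == 0) stop("slope factor K must be nonzero")
  s <- if (kind == "activation") -1 else 1
  1 / (1 + exp(s * (vm - vhalf) / k))
}

#' Hill steady-state gate for Ca2+-activated currents
#'
#' `1/(1 + (Ca_half/Ca)^n)`: increasing in Ca, 0.5 at `Ca = Ca_half`.
#' Used for the BK Ca2+ factor f_CaBK and the SK activation f_SK.
#'
#' @param ca intracellular Ca2+ (nM), > 0; may be a vector.
#' @param ca_half half-activation concentration (nM), > 0.
#' @param n Hill coefficient, >= 1.
#' @return gate value in (0, 1).
#' @examples
#' hill_gate(1700, 1700, 3)  # 0.5
#' @export
hill_gate <- function(ca, ca_half, n) {
  if (any(ca <= 0)) stop("Ca2+ concentration must be > 0")
  if (ca_half <= 0) stop("Ca_half must be > 0")
  if (n < 1) stop("Hill coefficient must be >= 1")
  1 / (1 + (ca_half / ca)^n)
}

#' Voltage-dependent gating time constants
#'
#' The three voltage-dependent time constants of the model (in seconds):
#' \describe{
#'   \item{mBK}{`-0.15021/(1 + exp(-(Vm + 46)/22.7)) + 0.1806`}
#'   \item{hNa}{`(4.5 cosh(arg/(3 Kh_Na)) + 0.75)/1000`}
#'   \item{mK}{`(5 cosh(arg/(2 Km_K)) + 0.75)/1000`}
#' }
#' where `arg` centers the cosh according to the parameter set's
#' `tau_convention` (see [neuron_parameters()]): `"literal"` uses
#' `Vm + Vhalf` with signed values, `"centered"` uses `Vm - Vhalf`, and
#' `"magnitude"` (default) uses `Vm + |Vhalf|`.
#'
#' @param vm membrane potential (mV); may be a vector.
#' @param kind one of `"hNa"`, `"mK"`, `"mBK"`.
#' @param params a [neuron_parameters()] object.
#' @return time constant(s) in seconds, strictly positive.
#' @examples
#' voltage_dependent_tau(-46, "mBK", neuron_parameters())  # 0.105495
#' @export
voltage_dependent_tau <- function(vm, kind = c("hNa", "mK", "mBK"),
                                  params = neuron_parameters()) {
  kind <- match.arg(kind)
  if (kind == "mBK")
    return(-0.15021 / (1 + exp(-(vm + 46) / 22.7)) + 0.1806)
  vhalf <- if (kind == "hNa") params$Vh_Na else params$Vm_K
  arg <- switch(params$tau_convention,
                literal   = vm + vhalf,
                centered  = vm - vhalf,
                magnitude = vm + abs(vhalf))
  a <- if (kind == "hNa") 4.5 else 5
  den <- if (kind == "hNa") 3 * params$Kh_Na else 2 * params$Km_K
  ch <- cosh(arg / den)
  if (params$tau_profile == "sech") (a / ch + 0.75) / 1000
  else (a * ch + 0.75) / 1000
}

#' Nernst reversal potential for Ca2+
#'
#' `E_Ca = 1000 R T / (z F) ln(Ca_e/Ca_i)` in mV, with R in J/(nmol K),
#' F in C/nmol and concentrations in nM.  Recomputed continuously during
#' simulation because Ca_i is dynamic.
#'
#' @param ca_i intracellular Ca2+ (nM), > 0; may be a vector.
#' @param ca_e external Ca2+ (nM), > 0.
#' @param temp temperature (K).
#' @param params a [neuron_parameters()] object (supplies R, F, z).
#' @return reversal potential (mV).
#' @examples
#' nernst_calcium(50, 2e6, 298.15)  # about 136 mV
#' @export
nernst_calcium <- function(ca_i, ca_e = NULL, temp, params = neuron_parameters()) {
  if (is.null(ca_e)) ca_e <- params$Ca_e
  if (any(ca_i <= 0) || any(ca_e <= 0)) stop("Ca2+ concentrations must be > 0")
  1000 * params$R * temp / (params$z * params$F) * log(ca_e / ca_i)
}
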