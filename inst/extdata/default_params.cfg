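# CIII neuron model parameters (mV, s, nS, pA, nF, nM, pL, K)
Cm = 0.01
G_Na = 80
G_K = 140
G_Ca = 3.5
G_BK = 6
G_SK = 0.31
G_L = 0.25
E_Na = 65
E_K = -75
E_L = -75
Vm_Na = -24.7
Km_Na = 3.4
Vh_Na = -41.2
Kh_Na = 4.2
Vm_K = -12
Km_K = 7
Vm_Ca = -23
Km_Ca = 6.5
Vh_Ca = -59
Kh_Ca = 12
Vm_BK = -28.3
Km_BK = 30
Ca_BK = 1700
n_BK = 3
Ca_SK = 800
n_SK = 3
tau_mNa = 1e-04
tau_mCa = 0.0035
tau_hCa = 0.095
tau_mSK = 0.04
F = 9.648535e-05
R = 8.31e-09
z = 2
Vol = 0.2
k_Ca = 403
Ca_min = 50
Ca_e = 2e+06
T0 = 298.15
rho_base = 1.3
phi_base = 3
tau_convention = magnitude
tau_profile = sech
# TRP current
trp.mode = dynamic
trp.G_LTRP = 0
trp.G_TRP_max = 1.2
trp.A = 1
trp.B = 1
trp.T_h = 290.15
trp.N = 2
trp.Ca_h = 700
trp.tau_mTRP = 0.002
trp.tau_hTRP = 10
trp.P_K = 1
trp.P_Ca = 0.4
trp.E_K_fix = -75
trp.E_Na_fix = 65
trp.E_Ca_star = 120
trp.activation_orientation = cold
trp.etrp_mode = dynamic_ECa
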