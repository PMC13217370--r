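# Shared fixtures: the printed kinetic/thermodynamic anchors of the
# probe-Pb(II) system and a few derived objects used across tests.

anchors <- list(
  dG0_rt  = -43.84,  # kJ/mol, room temperature
  dG0_hot = -35.65,  # kJ/mol, 60 C
  Ea_rt   = 76.32,   # kJ/mol
  Ea_hot  = 69.05,   # kJ/mol
  kf_rt   = 5.33e4,  # /M/s
  kf_hot  = 1.22e5,  # /M/s
  kr_rt   = 1.1e-3,  # /s (printed, 2 s.f.)
  kr_hot  = 3e-1,    # /s (printed, 1 s.f.)
  T_rt    = 298,
  T_hot   = 333,
  sigma_blank = 0.067,  # mA
  slope       = 0.307,  # mA/decade
  C_ref       = 2.43e-13 # M
)

anchor_rates_rt  <- function() rate_set(anchors$T_rt, anchors$kf_rt, anchors$kr_rt)
anchor_rates_hot <- function() rate_set(anchors$T_hot, anchors$kf_hot, anchors$kr_hot)

R_GAS <- 8.314462618
N_AVO <- 6.02214076e23
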