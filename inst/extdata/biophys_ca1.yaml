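# Biophysical parameter set for the reduced CA1 pyramidal-cell model.
# Passive properties and channel densities (S/cm2) per section class;
# calibrated so the median synthetic CA1 cell shows canonical CA1
# physiology (rest ~ -70 mV, somatic input resistance ~150 MOhm, 5-ms
# somatic rheobase of a few hundred pA, somatic voltage threshold in the
# mid -50s mV). See the methods vignette for the calibration procedure.
global:
  Ra: 150.0              # axial resistivity, Ohm*cm
  cm: 1.0                # specific capacitance, uF/cm2
  ena: 55.0              # mV
  ek: -90.0              # mV
  vT: -62.5              # kinetic voltage origin of the Na/K rate functions
  rate_scale: 1.0        # global q10-style scaling of all gating rates
  na_shift_ais_dist: -5.0  # Na activation shift in the distal AIS, mV
  shift_inactivation: false  # apply the shift to inactivation as well
defaults:
  g_pas: 1.0e-4          # S/cm2
  e_pas: -70.0           # mV
  gna: 0.0
  gk: 0.0
sections:
  soma:        {gna: 0.030, gk: 0.012}
  apical_prox: {gna: 0.005, gk: 0.002}
  apical_mid:  {}
  apical_dist: {}
  tuft:        {}
  basal:       {gna: 0.005, gk: 0.002}
  acd_stem:    {gna: 0.005, gk: 0.002}
  balance_stub: {gna: 0.005, gk: 0.002}
  hillock:     {gna: 0.180, gk: 0.015}
  ais_prox:    {gna: 0.340, gk: 0.030}
  ais_dist:    {gna: 0.510, gk: 0.045}
  axon:        {gna: 0.160, gk: 0.020}
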