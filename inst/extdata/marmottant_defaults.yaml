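# Frozen default parameter set for the Marmottant microbubble simulation.
# Shell parameters (elastic modulus, surface viscosity, resting surface
# tension) were frozen by calibrate_shell() against the expansion-ratio
# anchors 15/33/50 at 300/500/800 kPa and the stable-cavitation
# boundaries 85/205 kPa (250 kHz, 1.5 um resting diameter).
# Units are annotated in the key names.
version: 1
bubble:
  resting_radius_um: 0.75
gas:
  polytropic_exponent: 1.07
  vapor_pressure_kpa: 0.0
medium:
  density_kg_m3: 1000.0
  dynamic_viscosity_pa_s: 0.002
  sound_speed_m_s: 1500.0
  ambient_pressure_kpa: 101.325
  water_surface_tension_n_m: 0.073
shell:
  elastic_modulus_n_m: 0.020
  surface_viscosity_kg_s: 5.8e-9
  initial_surface_tension_n_m: 0.050
drive:
  center_frequency_khz: 250.0
  n_cycles: 50
  envelope: rectangular
thresholds:
  stable_lower: 1.1
  inertial_onset: 3.5
solver:
  rtol: 1.0e-8
  atol_radius_rel: 1.0e-12
  collapse_floor_rel: 0.05
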