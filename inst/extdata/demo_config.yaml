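# Demo configuration: same physics as the package defaults, shorter runs.
# Ladder mirrors the 7.0-10.0 range with a 1.0 pH-unit step used for the
# tricyclic-type weak bases; one Monte-Carlo step is one nominal ps.
pka_water: 9.0
pH_ladder: [7.0, 8.0, 9.0, 10.0]
n_replicates: 5
n_steps: 50000
exchange_period: 20
titration_period: 20
burn_in_fraction: 0.5
membrane:
  lipids_per_leaflet: 64
  box_xy: [62.0, 62.0]
  plane_offset: 18.0
  jitter_sd: 0.4
  deformation_amplitude: 1.5
  deformation_wavelength: 31.0
  oxygens_per_phosphate: 3
seed: 1
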