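# Example run configuration: the three packaged species in the 1.5-y/o
# stand, liberated with the field-trial gap radius of 0.5 m.
# Lengths in metres, angles in degrees, irradiance in umol m^-2 s^-1.
species:
  - name: Mallotus microcarpus
    tree:
      height: 1.26
      crown_volume: 0.04
      lw_ratio: 1.18
      leaf_area: 0.29
      lad: 6.72
      leaf_angle_fractions:
        angles: [15, 45, 75]
        fractions: [0.23, 0.48, 0.29]
    physiology:
      N_o: 94.28
      pmax_slope: 0.17
      R_d: 1.04
      quantum_yield: 0.03
      theta: 0.7
  - name: Mallotus paniculatus
    tree:
      height: 0.94
      crown_volume: 0.01
      lw_ratio: 2.00
      leaf_area: 0.06
      lad: 4.94
      leaf_angle_fractions:
        angles: [15, 45, 75]
        fractions: [0.13, 0.41, 0.46]
    physiology:
      N_o: 79.33
      pmax_slope: 0.10
      R_d: 0.24
      quantum_yield: 0.03
      theta: 0.7
  - name: Macaranga denticulata
    tree:
      height: 1.07
      crown_volume: 0.03
      lw_ratio: 1.42
      leaf_area: 0.11
      lad: 4.35
      leaf_angle_fractions:
        angles: [15, 45, 75]
        fractions: [0.37, 0.40, 0.24]
    physiology:
      N_o: 82.52
      pmax_slope: 0.18
      R_d: 0.53
      quantum_yield: 0.04
      theta: 0.7
stand:
  height: 1.40
  lai: 3.73
  leaf_angle_fractions: spherical
gap:
  radius: 0.5
sky:
  type: uoc
  n_elevation: 9
  n_azimuth: 12
  io: 1000
numerics:
  crown_grid: 16
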