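# Electrode placement conventions for the montage presets.
# Angles in degrees: theta = colatitude from the vertex (+z),
# phi = azimuth from the anterior axis (+x), +y = left.
# The anode angle approximates a left motor-cortex (C3-like) site and the
# cathode angle a right (contralateral) supraorbital site on a sphere; no
# 10-20 coordinate system is implemented.
pad_m1_so:
  pad_mm: 50
  anode:   { theta_deg: 45, phi_deg: 90 }
  cathode: { theta_deg: 70, phi_deg: -35 }
hd_4x1:
  disc_diameter_mm: 12
  ring_distance_mm: 60    # scalp-geodesic center-to-center distance
# Contact and conductor layer thicknesses (not constrained by the modeled
# physics; physically typical values, recorded here so they are auditable)
thickness:
  sponge_mm: 5
  gel_mm: 2
  conductor_mm: 1
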