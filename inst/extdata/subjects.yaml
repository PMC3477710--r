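# Illustrative "subject" head presets emulating inter-individual variation
# across three healthy adults: ~10% spread in outer head radius and skull
# thickness spanning 4-7 mm. F is the smallest head with the thinnest skull
# and CSF layer. All lengths in mm.
M1:
  outer_radius_mm: 92
  skin_mm: 7
  skull_mm: 7
  csf_mm: 3.2
  gray_mm: 3.0
M2:
  outer_radius_mm: 90
  skin_mm: 6.5
  skull_mm: 5.5
  csf_mm: 2.4
  gray_mm: 3.0
F:
  outer_radius_mm: 84
  skin_mm: 5.5
  skull_mm: 4.2
  csf_mm: 1.8
  gray_mm: 3.2
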