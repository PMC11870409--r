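name: synthetic_hornig_like
scenario: constitutive
units: absolute_concentration
conversion:
  cells_per_volume: 100000.0
  molar_mass: 110000.0
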