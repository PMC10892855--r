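inputs:
- name: muscle_contraction
  range:
  - 0.0
  - 10.0
  mfs:
    low:
      label: low
      center: 0.0
      sigma: 2.5
    medium:
      label: medium
      center: 5.0
      sigma: 2.5
    high:
      label: high
      center: 10.0
      sigma: 2.5
- name: resistive_torque
  range:
  - 0.0
  - 65.0
  mfs:
    very_low:
      label: very_low
      center: 0.0
      sigma: 8.125
    low:
      label: low
      center: 16.25
      sigma: 8.125
    medium:
      label: medium
      center: 32.5
      sigma: 8.125
    high:
      label: high
      center: 48.75
      sigma: 8.125
    very_high:
      label: very_high
      center: 65.0
      sigma: 8.125
- name: rom_margin
  range:
  - 0.0
  - 130.0
  mfs:
    none:
      label: none
      center: 0.0
      sigma: 21.666666666666668
    small:
      label: small
      center: 43.333333333333336
      sigma: 21.666666666666668
    large:
      label: large
      center: 86.666666666666671
      sigma: 21.666666666666668
    full:
      label: full
      center: 130.0
      sigma: 21.666666666666668
output:
  name: pain_level
  range:
  - 0.0
  - 10.0
  mfs:
    none:
      label: none
      center: 0.0
      sigma: 1.666666666666667
    low:
      label: low
      center: 3.333333333333333
      sigma: 1.666666666666667
    moderate:
      label: moderate
      center: 6.666666666666667
      sigma: 1.666666666666667
    severe:
      label: severe
      center: 10.0
      sigma: 1.666666666666667
grid_points: 1001
rules:
- muscle_contraction=low & resistive_torque=very_low & rom_margin=none => none
- muscle_contraction=medium & resistive_torque=very_low & rom_margin=none => low
- muscle_contraction=high & resistive_torque=very_low & rom_margin=none => moderate
- muscle_contraction=low & resistive_torque=low & rom_margin=none => none
- muscle_contraction=medium & resistive_torque=low & rom_margin=none => low
- muscle_contraction=high & resistive_torque=low & rom_margin=none => moderate
- muscle_contraction=low & resistive_torque=medium & rom_margin=none => low
- muscle_contraction=medium & resistive_torque=medium & rom_margin=none => moderate
- muscle_contraction=high & resistive_torque=medium & rom_margin=none => severe
- muscle_contraction=low & resistive_torque=high & rom_margin=none => low
- muscle_contraction=medium & resistive_torque=high & rom_margin=none => moderate
- muscle_contraction=high & resistive_torque=high & rom_margin=none => severe
- muscle_contraction=low & resistive_torque=very_high & rom_margin=none => moderate
- muscle_contraction=medium & resistive_torque=very_high & rom_margin=none => severe
- muscle_contraction=high & resistive_torque=very_high & rom_margin=none => severe
- muscle_contraction=low & resistive_torque=very_low & rom_margin=small => none
- muscle_contraction=medium & resistive_torque=very_low & rom_margin=small => none
- muscle_contraction=high & resistive_torque=very_low & rom_margin=small => low
- muscle_contraction=low & resistive_torque=low & rom_margin=small => none
- muscle_contraction=medium & resistive_torque=low & rom_margin=small => low
- muscle_contraction=high & resistive_torque=low & rom_margin=small => moderate
- muscle_contraction=low & resistive_torque=medium & rom_margin=small => none
- muscle_contraction=medium & resistive_torque=medium & rom_margin=small => low
- muscle_contraction=high & resistive_torque=medium & rom_margin=small => moderate
- muscle_contraction=low & resistive_torque=high & rom_margin=small => low
- muscle_contraction=medium & resistive_torque=high & rom_margin=small => moderate
- muscle_contraction=high & resistive_torque=high & rom_margin=small => severe
- muscle_contraction=low & resistive_torque=very_high & rom_margin=small => low
- muscle_contraction=medium & resistive_torque=very_high & rom_margin=small => moderate
- muscle_contraction=high & resistive_torque=very_high & rom_margin=small => severe
- muscle_contraction=low & resistive_torque=very_low & rom_margin=large => none
- muscle_contraction=medium & resistive_torque=very_low & rom_margin=large => none
- muscle_contraction=high & resistive_torque=very_low & rom_margin=large => low
- muscle_contraction=low & resistive_torque=low & rom_margin=large => none
- muscle_contraction=medium & resistive_torque=low & rom_margin=large => none
- muscle_contraction=high & resistive_torque=low & rom_margin=large => low
- muscle_contraction=low & resistive_torque=medium & rom_margin=large => none
- muscle_contraction=medium & resistive_torque=medium & rom_margin=large => low
- muscle_contraction=high & resistive_torque=medium & rom_margin=large => moderate
- muscle_contraction=low & resistive_torque=high & rom_margin=large => none
- muscle_contraction=medium & resistive_torque=high & rom_margin=large => low
- muscle_contraction=high & resistive_torque=high & rom_margin=large => moderate
- muscle_contraction=low & resistive_torque=very_high & rom_margin=large => low
- muscle_contraction=medium & resistive_torque=very_high & rom_margin=large => moderate
- muscle_contraction=high & resistive_torque=very_high & rom_margin=large => severe
- muscle_contraction=low & resistive_torque=very_low & rom_margin=full => none
- muscle_contraction=medium & resistive_torque=very_low & rom_margin=full => none
- muscle_contraction=high & resistive_torque=very_low & rom_margin=full => low
- muscle_contraction=low & resistive_torque=low & rom_margin=full => none
- muscle_contraction=medium & resistive_torque=low & rom_margin=full => none
- muscle_contraction=high & resistive_torque=low & rom_margin=full => low
- muscle_contraction=low & resistive_torque=medium & rom_margin=full => none
- muscle_contraction=medium & resistive_torque=medium & rom_margin=full => low
- muscle_contraction=high & resistive_torque=medium & rom_margin=full => moderate
- muscle_contraction=low & resistive_torque=high & rom_margin=full => none
- muscle_contraction=medium & resistive_torque=high & rom_margin=full => low
- muscle_contraction=high & resistive_torque=high & rom_margin=full => moderate
- muscle_contraction=low & resistive_torque=very_high & rom_margin=full => low
- muscle_contraction=medium & resistive_torque=very_high & rom_margin=full => moderate
- muscle_contraction=high & resistive_torque=very_high & rom_margin=full => severe
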