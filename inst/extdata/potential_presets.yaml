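doublewell_2kT:
  form: double_well
  barrier_height: 2.0
  half_separation: 5.0
doublewell_high_narrow:
  form: double_well
  barrier_height: 4.0
  half_separation: 4.0
doublewell_low:
  form: double_well
  barrier_height: 2.0
  half_separation: 4.0
doublewell_wide:
  form: double_well
  barrier_height: 4.0
  half_separation: 8.0
doublewell_shallow:
  form: double_well
  barrier_height: 1.0
  half_separation: 3.0
singlewell_flat:
  form: flat_well
  wall_height: 2.0
  halfwidth: 1.0
  wall_exponent: 4
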