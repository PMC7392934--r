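# Default transformer parameter sets: tympanic-membrane (pars tensa) and
# projected footplate areas in mm^2, ossicular lever ratio L1/L2,
# cochlear specific acoustic impedance in kPa s m^-1, air in Pa s m^-1.
species:
  sheep:
    A_TM: 44.2
    A_FP: 1.45
    lever_ratio: 2.47
    Z_cochlea_kPa: 56
    Z_air: 420
  human:
    A_TM: 68.3
    A_FP: 2.86
    lever_ratio: 1.25
    Z_cochlea_kPa: 56
    Z_air: 420
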