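# Scaled-down demonstration study: the reference volumes are about one
# fifth of the full calibration (the capillary densities are unchanged),
# so the complete phantom -> sectioning -> probes -> estimators -> report
# chain runs in a few seconds.
seed: 7
nPerGroup: 3
vwm: cavalieri
probes:
  t_mm: 1
  ap_mm2: 0.01
  blockSpacing: 0.06
  margin: 0.28
  planeOffset: 0.03
  fieldsPerSection: 4
  fieldSize: 0.1
  fieldSpread: 0.1
  frameSize: 0.08
cohort:
  regionDims:
    x_mm: 0.8
    y_mm: 0.65
  groups:
    wild_type:
      Vwm_mm3: 2.6
      L_m: 2.5131
      Vcap_mm3: 0.0180
      Scap_mm2: 21.578
    tg2576:
      Vwm_mm3: 2.49
      L_m: 1.3935
      Vcap_mm3: 0.013086
      Scap_mm2: 12.4753
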