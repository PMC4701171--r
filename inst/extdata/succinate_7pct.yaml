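treatment:
  cSource: succinate
  initialO2VolPct: 7.0
  initialNO3: 0.002
  inoculum: 2.2e+08
  volHeadspace: 0.07
  volLiquid: 0.05
  samplingSchedule:
  - 0.0
  - 3.0
  - 6.0
  - 9.0
  - 12.0
  - 15.0
  - 18.0
  - 21.0
  - 24.0
  - 27.0
  - 30.0
  - 33.0
  - 36.0
  - 39.0
  - 42.0
  - 45.0
  - 48.0
  - 51.0
  - 54.0
  - 57.0
  - 60.0
  - 63.0
  - 66.0
  - 69.0
  - 72.0
  - 75.0
  - 78.0
  - 81.0
  - 84.0
  - 87.0
  - 90.0
  - 93.0
  - 96.0
  - 99.0
  - 102.0
  - 105.0
  - 108.0
  - 111.0
  - 114.0
  - 117.0
  - 120.0
  - 123.0
  - 126.0
  - 129.0
  - 132.0
  - 135.0
  - 138.0
  - 141.0
  - 144.0
  - 147.0
  - 150.0
  tEnd: 150.0
  rtol: 1.0e-08
  atol: 1.0e-16
params:
  veMaxTCA: 9.34e-15
  veMaxO2: 4.42e-15
  veMaxNO3: 9.34e-15
  veMaxNO2: 2.01e-15
  veMin: 1.95e-17
  yieldO2: 4.97e+13
  yieldNOx: 1.52e+13
  veMaxNO: 3.56e-15
  veMaxN2O: 5.5e-15
  o2ThresholdNar: 5.95e-05
  o2ThresholdNir: 9.75e-06
  rNa: 0.035
  rNi: 0.004
  kmO2: 2.25e-07
  kmNO3: 5.0e-06
  kmNO2: 4.13e-06
  kmN2O: 5.93e-07
  k1NO: 8.0e-14
  k2NO: 3.4e-08
  kHO2: 0.0014
  kHNO: 0.0021
  kHN2O: 0.056
  kHN2: 0.00035
  kt: 3.6
  dilutionD: 0.015
  o2Leak: 2.92e-09
  samplingDuration: 0.017
  gasConstant: 0.083
  temperature: 293.15
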