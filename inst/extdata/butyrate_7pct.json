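{
  "treatment": {
    "cSource": "butyrate",
    "initialO2VolPct": 7,
    "initialNO3": 0.002,
    "inoculum": 220000000,
    "volHeadspace": 0.07,
    "volLiquid": 0.05,
    "samplingSchedule": [0, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30, 33, 36, 39, 42, 45, 48, 51, 54, 57, 60, 63, 66, 69, 72, 75, 78, 81, 84, 87, 90, 93, 96, 99, 102, 105, 108, 111, 114, 117, 120, 123, 126, 129, 132, 135, 138, 141, 144, 147, 150],
    "tEnd": 150,
    "rtol": 1e-08,
    "atol": 1e-16
  },
  "params": {
    "veMaxTCA": 1e-14,
    "veMaxO2": 4.22e-15,
    "veMaxNO3": 1e-14,
    "veMaxNO2": 2.65e-15,
    "veMin": 1.87e-17,
    "yieldO2": 27400000000000,
    "yieldNOx": 11200000000000,
    "veMaxNO": 3.56e-15,
    "veMaxN2O": 5.5e-15,
    "o2ThresholdNar": 5.95e-05,
    "o2ThresholdNir": 9.75e-06,
    "rNa": 0.035,
    "rNi": 0.004,
    "kmO2": 2.25e-07,
    "kmNO3": 5e-06,
    "kmNO2": 4.13e-06,
    "kmN2O": 5.93e-07,
    "k1NO": 8e-14,
    "k2NO": 3.4e-08,
    "kHO2": 0.0014,
    "kHNO": 0.0021,
    "kHN2O": 0.056,
    "kHN2": 0.00035,
    "kt": 3.6,
    "dilutionD": 0.015,
    "o2Leak": 2.92e-09,
    "samplingDuration": 0.017,
    "gasConstant": 0.083,
    "temperature": 293.15
  }
}
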