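{
  "description": "Reference canonical discriminant functions for Griffon Bruxellois CM/SM screening: two CM functions (3-group analysis) and one SM function (2-group analysis). Coefficients apply to measurements in mm (lines) and degrees (angles).",
  "cm_function_1": {
    "coefficients": { "f_diameter": -0.351, "angle2": 0.112 },
    "constant": 6.968
  },
  "cm_function_2": {
    "coefficients": { "f_diameter": 0.423, "angle2": 0.118 },
    "constant": -26.357
  },
  "sm_function": {
    "coefficients": { "f_diameter": 0.410, "angle5": -0.150 },
    "constant": -10.757
  }
}
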