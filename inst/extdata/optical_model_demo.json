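{
  "comment": "Demonstration optical model for the four-wavelength LED set. Extinction coefficients are representative values converted from base-10 molar extinction compilations to the natural-log convention in mm^-1 uM^-1 (multiply cm^-1 M^-1 values by ln(10) * 1e-7); pathlengths are plausible effective values in mm. Synthetic/demo values: calibrate against a measured extinction table and tissue optical properties before quantitative use.",
  "wavelengths_nm": [478, 588, 610, 625],
  "extinction": [
    [3.062e-03, 4.375e-03],
    [5.641e-03, 4.835e-03],
    [2.763e-04, 2.187e-03],
    [1.151e-04, 1.358e-03]
  ],
  "extinction_columns": ["hbo", "hbr"],
  "pathlength_mm": [1.2, 1.5, 3.5, 4.0]
}
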