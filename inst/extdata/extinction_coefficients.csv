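# Molar extinction coefficients of hemoglobin (Prahl/Cope compilation),
# base-10, units M^-1 cm^-1. Converted in code to natural-log basis
# uM^-1 mm^-1 for the modified Beer-Lambert law.
wavelength_nm,chromophore,epsilon_molar_log10
690,o2hb,276
690,hhb,2051.96
830,o2hb,974
830,hhb,693.04
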