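# Snapshot table of material models used by the simulation study.
# Reference wavelength 0.165312267 nm = 7.5 keV.
#
# delta entries are omitted where the stoichiometric electron density fixes
# them (delta = lambda^2 r0 rho_e / 2pi, exact far from absorption edges);
# beta entries are representative tabulated magnitudes at 7.5 keV chosen so
# that the 67.5/32.5 water/hemoglobin blood mixture has
# C' = beta/(delta lambda^2) = 0.1326 nm^-2 at the reference energy.
# Edit freely; nothing in the package hard-codes these numbers.
water:
  formula: H2O
  mass_density: 1.0
  beta: 1.300e-8
  wavelength_ref: 0.165312267
hemoglobin:
  formula: C2932H4724N828O840S8Fe4
  mass_density: 1.335
  beta: 2.295e-8
  wavelength_ref: 0.165312267
paraffin:
  formula: C30H62
  mass_density: 0.9
  beta: 5.467e-9
  wavelength_ref: 0.165312267
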