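# Bundled material constants (single-wavelength effective values, ~sodium D,
# room temperature). All entries are literature stand-ins with per-entry
# citations; densities in g/mL, specific volumes in mL/g.
water:
  "n": 1.3330
  rho: 0.997
  provenance: "standard sodium-D value; density of water at 23 C (CRC Handbook)"
triolein:
  "n": 1.4676
  rho: 0.9078
  provenance: "neutral lipid triolein, literature values (CRC Handbook / lipid data tables)"
lactose:
  "n": 1.533
  rho: 1.525
  provenance: "alpha-lactose, approximate crystal constants (CRC Handbook)"
casein:
  theta: 0.736
  R: 0.2469
  provenance: "bovine casein: PSV from densimetry literature; R back-computed from dn/dc = 0.186 mL/g via the Biot relation at n1 = 1.3330"
whey_protein:
  theta: 0.735
  R: 0.2462
  provenance: "bovine whey proteins: PSV from densimetry literature; R back-computed from dn/dc = 0.185 mL/g via the Biot relation at n1 = 1.3330"
soybean_oil:
  "n": 1.4729
  rho: 0.917
  provenance: "refined soybean oil, literature values (CRC Handbook)"
palmitic_acid:
  "n": 1.4335
  rho: 0.853
  provenance: "palmitic acid (16:0), liquid-state literature values, approximate"
stearic_acid:
  "n": 1.4337
  rho: 0.850
  provenance: "stearic acid (18:0), liquid-state literature values, approximate"
oleic_acid:
  "n": 1.4582
  rho: 0.895
  provenance: "oleic acid (18:1 n-9), CRC Handbook"
dha:
  "n": 1.5017
  rho: 0.943
  provenance: "docosahexaenoic acid (22:6 n-3), literature values, approximate"
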