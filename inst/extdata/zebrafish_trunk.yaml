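# Larval zebrafish (96 hpf) trunk tissue: binary protein + lipid solute in
# water. Protein parameters are the trunk-tissue sequence-derived values;
# the lipid is represented by triolein constants as a stand-in for the
# tissue lipid pool. Composition distributions: relative lipid volume
# fraction x_lip ~ T(0.220, 0.022), water volume fraction
# phi1 ~ T(0.860, 0.006), both truncated to [0, 1].
solvent:
  n1: 1.3330
  rho1: 0.997
components:
  trunk_protein:
    alpha: 0.1971
    dalpha: 0.0033
    theta: 0.734
    dtheta: 0.009
    x: 0.780
  triolein:
    "n": 1.4676
    rho: 0.9078
    x: 0.220
x_sd: 0.022
phi1_mean: 0.860
phi1_sd: 0.006
N0: 100000
Nv: 1000
ns_model: binomial
dm_rel: 0
seed: 421
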