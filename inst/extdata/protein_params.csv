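set,alpha_W,dalpha_W,alpha_B,dalpha_B,theta,dtheta
human_proteome_zhao,0.1899,0.0030,NA,NA,0.735,0.010
human_proteome,0.188,0.004,0.197,0.004,0.734,0.012
zebrafish_proteome_zhao,0.1904,0.0030,NA,NA,0.735,0.010
zebrafish_proteome,0.1887,0.0031,0.1974,0.0034,0.732,0.010
zebrafish_trunk,0.1883,0.0029,0.1971,0.0033,0.734,0.009
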