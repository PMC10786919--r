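name,kd_nM,cell_ec50_0pct_uM,cell_ec50_10pct_uM,prolif_on_uM,prolif_off_uM,solubility_uM
MP-081,5.0,0.47,0.88,2.33,2.8,105
MP-040,27.1,0.036,0.75,1.22,>49.75,P.B.
MP-467,,,0.030,0.013,>>50,
MP-769,,,>50,,,
MP-042,,,0.28,1.5,31,150
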