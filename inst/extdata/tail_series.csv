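name,tail_codes,series_class,kd_nM,cell_ec50_0pct_uM,cell_ec50_10pct_uM,tail_propensity,helicity_pct,solubility_uM,c_term
MP-081,S A A,template,5.0,0.47,0.88,High,48.35,105.3,amide
MP-685,A A A A A,polyA,8.2,0.11,0.32,High,28.3,N.D.,amide
MP-032,A A A A A A,polyA,5.0,0.15,0.29,High,34.6,P.B.,amide
MP-464,A A A A A dA,polyA,31,0.49,0.29,High,32,157,amide
MP-470,A A A A A A A,polyA,3.3,0.06,0.53,High,44,N.D.,amide
MP-471,A A A A A A A,polyA,6.7,0.10,0.60,High,40,N.D.,amide
MP-759,A A A A A A A A A,polyA,6.1,0.10,4.2,High,27.55,15,amide
MP-684,A A A,cleaved_tail,11.5,0.25,1.7,High,32.6,N.D.,free_acid
MP-688,A A A A A A,polyA,30,0.16,1.3,High,49.8,N.D.,amide
ALRN-6924,A A A A A dA,polyA,2.5,0.14,0.32,High,51.25,P.B.,amide
MP-413,A Aib Aib Aib Aib Aib,helical_tail,1.7,0.45,0.71,High,N.D.,N.D.,amide
MP-966,A Q A A A dA,helical_tail,45.9,0.39,1.0,High,N.D.,160,amide
MP-425,A A dA A A dA,nonhelical_tail,4.2,1.0,2.6,Low,42.3,185,amide
MP-056,A dA A dA A dA,nonhelical_tail,1.5,2.7,6.0,Low,22.23,157,amide
MP-443,A Sar Sar Sar Sar Sar,nonhelical_tail,1.5,5.4,10,Low,30.45,180,amide
MP-289,G G G G G G,nonhelical_tail,9.0,3.6,16,Low,24.33,142,amide
MP-093,P P P P P P,nonhelical_tail,132,15,>50,Low,16.5,156,amide
MP-094,P P P P P P,nonhelical_tail,3.9,5.9,1.9,Low,18.7,158,amide
MP-896,dP dP dP dP dP dP,nonhelical_tail,11,>50,>50,Low,19.15,P.B.,amide
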