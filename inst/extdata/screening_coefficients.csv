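response,term,coefficient
rd_purity,(Intercept),-0.12
rd_purity,X1,3.382e-4
rd_purity,X9,1.824e-3
rd_purity,X10,1.869e-4
rd_purity,Z5,3.971e-3
rd_purity,Z6,-8.607e-5
total_saponin_purity,(Intercept),0.76
total_saponin_purity,X1,2.203e-3
total_saponin_purity,Z1,0.0103
total_saponin_purity,Z2,5.291e-3
total_saponin_purity,Z4,-0.0111
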