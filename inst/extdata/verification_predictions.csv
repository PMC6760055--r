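batch_id,X1,X9,X10,predicted_rd_purity_pct,predicted_tsp_pct
PN18,88,56,133,4.70,86.50
PN20,90,60,120,4.83,89.81
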