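component,estimator,n_states,value,sigma
A_EM,MC,NA,48,3
dA_em_iem,TI,118,-167.316,0.001
dA_em_iem,MBAR,118,-167.07,0.03
dA_iem_solid,TI,600,-101.656,0.002
dA_iem_solid,MBAR,600,-101.644,0.002
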