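component,estimator,n_states,value,sigma
mu_em,MC,NA,9.3,0
mu_ffoff,MBAR,118,65.7409,0.0009
mu_restraining,MBAR,600,94.3,0.2
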