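mole_fraction,volume,n_solute,n_solvent,mu_ex,sigma
2.000e-03,3035.99,2,99998,-16.80,0.05
6.666e-03,911.17,2,30002,-15.88,0.04
7.999e-03,759.33,2,25000,-15.51,0.05
9.998e-03,911.45,3,30003,-15.65,0.04
9.999e-03,607.59,2,20000,-15.47,0.05
1.3330e-02,911.72,4,30004,-15.77,0.04
1.3332e-02,455.84,2,15000,-15.61,0.04
1.666e-02,912.00,5,30005,-15.96,0.05
1.9992e-02,912.27,6,30006,-15.78,0.04
1.9996e-02,304.01,2,10000,-15.62,0.05
3.998e-02,152.25,2,5000,-15.41,0.06
1.996e-01,30.835,2,1000,-16.37,0.05
2.991e-01,31.069,3,1000,-16.40,0.06
3.984e-01,31.309,4,1000,-16.62,0.06
4.975e-01,31.547,5,1000,-17.1,0.1
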