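{"weight":{"slope":0.000625,"intercept":2.72738781525498e-17,"r_squared":1,"n_points":2,"valid_range":[0,1600],"kind":"weight","fitted_on":"2026-09-26"},"chlorophyll":{"slope":4,"intercept":-0,"r_squared":1,"n_points":2,"valid_range":[0.05,0.25],"kind":"chlorophyll","fitted_on":"2026-09-26"},"anthocyanin":{"slope":-7.30769230769231,"intercept":1.85384615384615,"r_squared":1,"n_points":2,"valid_range":[-0.02,0.24],"kind":"anthocyanin","fitted_on":"2026-09-26"}}
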