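measure,band_lo,band_hi,cutoff,percentile,worse
VISM,4y0m,14y11m,0.60,5,lower
NOISE,4y0m,14y11m,0.60,5,lower
OVERL,4y0m,14y11m,0.60,5,lower
VIEW,4y0m,14y11m,0.60,5,lower
DEVOS,4y0m,14y11m,0.60,5,lower
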