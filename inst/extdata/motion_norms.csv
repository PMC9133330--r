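measure,band_lo,band_hi,cutoff,percentile,worse
GM,4y3m,4y7m,0.78,10,higher
GM,4y9m,5y8m,0.69,10,higher
GM,5y10m,7y4m,0.46,10,higher
MDF,4y3m,4y7m,0.45,10,lower
MDF,4y9m,5y8m,0.63,10,lower
MDF,5y10m,7y4m,0.74,10,lower
MS,4y3m,4y7m,23.80,10,higher
MS,4y9m,5y8m,20.00,10,higher
MS,5y10m,7y4m,12.49,10,higher
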