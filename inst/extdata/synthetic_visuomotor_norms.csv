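measure,band_lo,band_hi,cutoff,percentile,worse
BEERY,4y0m,14y11m,81,10,lower
MOSAICS,4y0m,14y11m,6,10,lower
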