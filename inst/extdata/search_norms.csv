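measure,band_lo,band_hi,cutoff,percentile,worse
search_time_5items,4y3m,4y7m,1.38,10,higher
search_time_5items,4y9m,5y8m,1.23,10,higher
search_time_5items,5y10m,7y4m,1.09,10,higher
search_time_10items,4y3m,4y7m,2.75,10,higher
search_time_10items,4y9m,5y8m,2.20,10,higher
search_time_10items,5y10m,7y4m,2.66,10,higher
search_time_20items,4y3m,4y7m,5.91,10,higher
search_time_20items,4y9m,5y8m,5.47,10,higher
search_time_20items,5y10m,7y4m,4.16,10,higher
response_time,4y3m,4y7m,2.54,10,higher
response_time,4y9m,5y8m,2.03,10,higher
response_time,5y10m,7y4m,1.70,10,higher
total_errors,4y3m,4y7m,2,10,higher
total_errors,4y9m,5y8m,1,10,higher
total_errors,5y10m,7y4m,1,10,higher
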