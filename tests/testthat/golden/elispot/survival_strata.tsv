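group	n	events	median_months
high	            3	            2	        34.76
low	            1	            0	NA
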