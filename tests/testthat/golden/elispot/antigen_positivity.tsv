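subject_id	n_positive_antigens
S01	4
S02	6
S03	3
S04	1
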