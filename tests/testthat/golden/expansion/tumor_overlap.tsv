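subject_id	n_specific	n_overlap	fraction
S01	17	2	0.117647058824
S02	17	2	0.117647058824
S03	17	2	0.117647058824
S04	17	2	0.117647058824
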