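v_gene	cdr3_aa	n_subjects	subjects	shared_antigens	antigens_intersect
TCRBV09.01.01	CASSYQIIYGHLLKFTNF	2	S01,S02	G12V	TRUE
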