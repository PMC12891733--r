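subject_id	mode	delta	threshold	responder	significant_change	baseline_value	peak_week	max_fold
S01	pooled_average	26.8888888889	12.6771664115	TRUE	TRUE	51.5555555556	16	1.52155172414
S02	pooled_average	38.6666666667	12.6771664115	TRUE	TRUE	42.2777777778	8	1.91458607096
S03	pooled_average	29.7222222222	12.6771664115	TRUE	TRUE	51.9444444444	16	1.57219251337
S04	pooled_average	           11	12.6771664115	FALSE	FALSE	46.6111111111	16	1.23599523242
S01	tumor_matched	           64	 20.276576593	TRUE	TRUE	           45	12	2.42222222222
S02	tumor_matched	28.3333333333	 20.276576593	TRUE	TRUE	57.3333333333	4	1.49418604651
S03	tumor_matched	73.6666666667	 20.276576593	TRUE	TRUE	           40	16	2.84166666667
S04	tumor_matched	28.6666666667	 20.276576593	TRUE	TRUE	           46	16	 1.6231884058
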