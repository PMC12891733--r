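subject_id	v_gene	cdr3_aa	antigens	n_antigens	cross_reactive
S01	TCRBV24.01.01	CASSAMHHHIYSWVFAF	G12D	1	FALSE
S01	TCRBV17.01.01	CASSCHYFYMF	G12C	1	FALSE
S01	TCRBV12.01.01	CASSDAVKETHRMF	G12R	1	FALSE
S01	TCRBV05.01.01	CASSEKLVTHQQQKF	G12D	1	FALSE
S01	TCRBV01.01.01	CASSIMKICQKNPF	G12C	1	FALSE
S01	TCRBV20.01.01	CASSIRRYEPDHF	G12R,G12V	2	TRUE
S01	TCRBV05.01.01	CASSKKQPHTNHF	G12A	1	FALSE
S01	TCRBV16.01.01	CASSNRDHCMQVKEF	G12V	1	FALSE
S01	TCRBV25.01.01	CASSNVNPSKAINF	G13D	1	FALSE
S01	TCRBV11.01.01	CASSPFALIQF	G12V	1	FALSE
S01	TCRBV11.01.01	CASSQRAVEAF	G12R	1	FALSE
S01	TCRBV27.01.01	CASSSEKLILF	G13D	1	FALSE
S01	TCRBV28.01.01	CASSSIPIQPMCYTGEWF	G12A	1	FALSE
S01	TCRBV05.01.01	CASSSMERDF	G13D	1	FALSE
S01	TCRBV22.01.01	CASSVAKWETRAHTPF	G12C,G12V	2	TRUE
S01	TCRBV14.01.01	CASSWGAALCTHNF	G12D	1	FALSE
S01	TCRBV09.01.01	CASSYQIIYGHLLKFTNF	G12V	1	FALSE
S02	TCRBV13.01.01	CASSCSGGWKIKWGMKF	G12R	1	FALSE
S02	TCRBV14.01.01	CASSCWSWNAHDPDLF	G13D	1	FALSE
S02	TCRBV30.01.01	CASSHLPYWPVCGTF	G12R	1	FALSE
S02	TCRBV20.01.01	CASSIANMFF	G13D	1	FALSE
S02	TCRBV25.01.01	CASSIPFMIKCMPLWF	G12D	1	FALSE
S02	TCRBV16.01.01	CASSMIHRYWF	G13D	1	FALSE
S02	TCRBV19.01.01	CASSNDLGGEWPWF	G12C,G12V	2	TRUE
S02	TCRBV05.01.01	CASSQEHGDPGMLNDSF	G12V	1	FALSE
S02	TCRBV16.01.01	CASSQHGRNAWNAVCF	G12R	1	FALSE
S02	TCRBV19.01.01	CASSRDIHVLYPLNMWF	G12A,G12V	2	TRUE
S02	TCRBV24.01.01	CASSRQWHFVWMPPTYF	G12C	1	FALSE
S02	TCRBV10.01.01	CASSSFDLNHPF	G12D	1	FALSE
S02	TCRBV20.01.01	CASSSIPMMKEPRAHF	G12A	1	FALSE
S02	TCRBV19.01.01	CASSTNCLDMF	G12A,G12C	2	TRUE
S02	TCRBV26.01.01	CASSTSRDLFKSWF	G12A	1	FALSE
S02	TCRBV21.01.01	CASSVGEWHSMGKKAMAF	G12C	1	FALSE
S02	TCRBV09.01.01	CASSYQIIYGHLLKFTNF	G12V	1	FALSE
S03	TCRBV10.01.01	CASSAEEVNKAF	G12C,G13D	2	TRUE
S03	TCRBV30.01.01	CASSAHTKQAKAVWMIQF	G12C	1	FALSE
S03	TCRBV19.01.01	CASSCIDTIEQYSSYRF	G12R	1	FALSE
S03	TCRBV26.01.01	CASSCMREEYQNILWTVF	G12R	1	FALSE
S03	TCRBV05.01.01	CASSFCARWMKTMF	G12R	1	FALSE
S03	TCRBV03.01.01	CASSFHWQDCF	G12A	1	FALSE
S03	TCRBV06.01.01	CASSFINGDIFFRELVEF	G13D	1	FALSE
S03	TCRBV28.01.01	CASSFNIIIF	G12A	1	FALSE
S03	TCRBV18.01.01	CASSFTQPIAMYEWGF	G12D	1	FALSE
S03	TCRBV26.01.01	CASSLEKYDRFLHF	G12A	1	FALSE
S03	TCRBV06.01.01	CASSLMLEYKCTKF	G12C,G12V	2	TRUE
S03	TCRBV23.01.01	CASSMNECNVTNHQWF	G12D	1	FALSE
S03	TCRBV23.01.01	CASSMQECYMWELREF	G12C,G12R	2	TRUE
S03	TCRBV18.01.01	CASSPLAHREWTNYNHF	G12V	1	FALSE
S03	TCRBV03.01.01	CASSQMWVCPTQFMQMEF	G12V	1	FALSE
S03	TCRBV15.01.01	CASSSTWLQCCSF	G12D	1	FALSE
S03	TCRBV01.01.01	CASSYCRRREF	G13D	1	FALSE
S04	TCRBV13.01.01	CASSAPTRVWKYMEGF	G12A	1	FALSE
S04	TCRBV30.01.01	CASSCCNMMHF	G12V	1	FALSE
S04	TCRBV04.01.01	CASSCHKEFQGMQSNRLF	G12R	1	FALSE
S04	TCRBV29.01.01	CASSCQPKGF	G12A	1	FALSE
S04	TCRBV13.01.01	CASSEIFRQFF	G12C	1	FALSE
S04	TCRBV16.01.01	CASSERLWQSINRAERF	G12C,G13D	2	TRUE
S04	TCRBV21.01.01	CASSFAGYWGDVCGQAF	G13D	1	FALSE
S04	TCRBV01.01.01	CASSFHHKLF	G12R	1	FALSE
S04	TCRBV19.01.01	CASSGRTTLNRVVCPF	G12C	1	FALSE
S04	TCRBV17.01.01	CASSIMFKMF	G12V	1	FALSE
S04	TCRBV11.01.01	CASSKKLNKRSYISCF	G12A,G12R	2	TRUE
S04	TCRBV27.01.01	CASSPWKQINWF	G13D	1	FALSE
S04	TCRBV21.01.01	CASSSVTNDF	G12D,G12R	2	TRUE
S04	TCRBV09.01.01	CASSSWKPAMWTMGLVF	G12D	1	FALSE
S04	TCRBV13.01.01	CASSVPNIVHEHTKMCPF	G12R	1	FALSE
S04	TCRBV02.01.01	CASSWFDFGDVMQF	G13D	1	FALSE
S04	TCRBV24.01.01	CASSWFFGPF	G12D	1	FALSE
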