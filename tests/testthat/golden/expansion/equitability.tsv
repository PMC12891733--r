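subject_id	condition	equitability
S01	baseline	0.200042136923
S01	vehicle_only	0.210007665276
S01	control_peptide	0.216632873681
S01	G12V	0.20041037978
S01	G12A	0.200834093613
S01	G12R	0.207918246064
S01	G12C	0.203885581991
S01	G12D	0.204711081311
S01	G13D	0.206683704892
S01	tumor_tissue	0.158196030565
S02	baseline	0.188464050349
S02	vehicle_only	0.184549568979
S02	control_peptide	0.18615166419
S02	G12V	0.178043519491
S02	G12A	0.175854034464
S02	G12R	0.178048815758
S02	G12C	0.186666580782
S02	G12D	0.177466577877
S02	G13D	0.177906690296
S02	tumor_tissue	0.142566374109
S03	baseline	0.18666943265
S03	vehicle_only	0.198072352715
S03	control_peptide	0.192841786411
S03	G12V	0.185594038991
S03	G12A	0.188436124065
S03	G12R	0.188583851195
S03	G12C	0.195318676144
S03	G12D	0.195737425162
S03	G13D	0.186970137739
S03	tumor_tissue	0.149660357047
S04	baseline	0.205579850793
S04	vehicle_only	0.212400257937
S04	control_peptide	0.206813003349
S04	G12V	0.19741734627
S04	G12A	0.205177207693
S04	G12R	 0.2071948969
S04	G12C	0.19869121545
S04	G12D	0.202400259708
S04	G13D	 0.1993599195
S04	tumor_tissue	0.144930371328
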