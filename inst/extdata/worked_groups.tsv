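# accession-to-group assignment
# columns: accession	group
accession	group
acc01	MGL
acc02	MGL
acc03	MGL
acc04	MGL
acc05	MGL
acc06	MGL
acc07	MGL
acc08	MGL
acc09	SI
acc10	SI
acc11	SI
acc12	SI
acc13	SI
acc14	SI
acc15	QTP
acc16	QTP
acc17	QTP
acc18	QTP
acc19	QTP
acc20	QTP
acc21	QTP
acc22	QTP
acc23	QTP
acc24	QTP
acc25	QTP
acc26	QTP
acc27	QTP
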