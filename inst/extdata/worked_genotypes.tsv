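# codominant genotypes, cell = a1/a2 or .
# columns: accession	L01	L02	L03	L04	L05	L06	L07	L08	L09	L10
accession	L01	L02	L03	L04	L05	L06	L07	L08	L09	L10
acc01	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/1
acc02	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc03	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc04	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc05	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc06	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc07	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc08	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc09	1/2	1/2	1/2	1/2	1/2	1/2	1/1	1/1	1/1	1/1
acc10	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc11	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc12	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc13	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc14	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc15	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/2	1/2
acc16	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc17	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc18	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc19	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc20	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc21	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc22	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc23	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc24	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc25	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc26	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
acc27	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1
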