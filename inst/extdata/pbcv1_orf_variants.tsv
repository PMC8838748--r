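name	start	end	length	n_variable_sites	n_snps_found
a001L	280	549	270	2	2
A014R	8255	12364	4110	1	3
A025/027/029L	16432	20511	4080	2	2
A064R	34956	36872	1917	3	7
A075bL	39078	39920	843	2	6
A078R	42007	42183	177	2	5
A081L	43192	43761	570	2	3
A122/123R	62145	66176	4032	14	32
A140/145R	73107	76490	3384	7	30
A162L	81717	82952	1236	1	4
A256/257L	129608	132121	2514	1	5
A314R	157306	157548	243	2	8
A416R	202802	203368	567	2	5
A478L	230676	231608	933	1	4
A533R	253765	254889	1125	2	5
A537L	255643	256440	798	1	5
A540L	257089	260859	3771	20	50
A689L	328590	329015	426	2	3
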