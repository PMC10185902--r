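clade	rsid	position	mutation	n_tested
O1a1	rs79011057	15870505	C > -	8
O1a1	rs75465866	14101642	T > -	8
O1a1a	rs756897195	14444770	TTG > -	5
O1a1a1	rs776778598	19623371	GAA > -	3
O1b	rs200942940	12416056	C > -	8
O1b1	rs760314663	20774821	C > -	6
O1b1a	rs749761428	6796839	- > T	5
O1b1a1a	rs774008684	17452553	AAGA > -	3
O1b1a1a1a1a1	rs774805227	16596493	A > -	1
O1b2	rs201451931	7765543	T > -	4
O1b2a1a	rs200704310	12173532	TAA > -	3
O2a	rs201101541	16693737	- > C	10
O2a1a1	rs2044026501	16599674	A > -	2
O2a1b	rs1569514296	13477987	TAC > -	6
O2a1b1a	rs754348496	12420208	T > -	4
O2a1b1a1a1a1	rs759556853	12663077	T > -	3
O2a2a	rs768760512	13353588	- > T	8
O2a2a1a	rs776330196	13497196	T > -	6
O2a2b	rs79480324	14153309	A > -	7
O2a2b1a1a1a4a	rs796937681	12821143	- > A	2
O2a2b1a2a	rs201510546	8044404	TAAAG > -	5
O2a2b1a2a1a	rs762474604	15235863	AT > -	2
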