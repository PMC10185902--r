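name	haplogroup	position	ancestral	derived
SYN_C	C	2001000	C	T
SYN_N	N	2002000	G	A
SYN_NO	NO	2003000	T	C
SYN_O	O	2004000	A	G
SYN_O1	O1	2005000	C	T
SYN_O1a	O1a	2006000	G	A
SYN_O1a1	O1a1	2007000	T	C
SYN_O1a1a	O1a1a	2008000	A	G
SYN_O1a1a1	O1a1a1	2009000	C	T
SYN_O1b	O1b	2010000	G	A
SYN_O1b1	O1b1	2011000	T	C
SYN_O1b1a	O1b1a	2012000	A	G
SYN_O1b1a1	O1b1a1	2013000	C	T
SYN_O1b1a1a	O1b1a1a	2014000	G	A
SYN_O1b1a1a1	O1b1a1a1	2015000	T	C
SYN_O1b1a1a1a	O1b1a1a1a	2016000	A	G
SYN_O1b1a1a1a1	O1b1a1a1a1	2017000	C	T
SYN_O1b1a1a1a1a	O1b1a1a1a1a	2018000	G	A
SYN_O1b1a1a1a1a1	O1b1a1a1a1a1	2019000	T	C
SYN_O1b1a1a1a1a1a	O1b1a1a1a1a1a	2020000	A	G
SYN_O1b1a1a1a1a1a1	O1b1a1a1a1a1a1	2021000	C	T
SYN_O1b1a1a1a1a1a1a	O1b1a1a1a1a1a1a	2022000	G	A
SYN_O1b1a1a1a1a1a1a1	O1b1a1a1a1a1a1a1	2023000	T	C
SYN_O1b1a1a1a1a1a1a1a	O1b1a1a1a1a1a1a1a	2024000	A	G
SYN_O1b1a2	O1b1a2	2025000	C	T
SYN_O1b2	O1b2	2026000	G	A
SYN_O1b2a	O1b2a	2027000	T	C
SYN_O1b2a1	O1b2a1	2028000	A	G
SYN_O1b2a1a	O1b2a1a	2029000	C	T
SYN_O2	O2	2030000	G	A
SYN_O2a	O2a	2031000	T	C
SYN_O2a1	O2a1	2032000	A	G
SYN_O2a1a	O2a1a	2033000	C	T
SYN_O2a1a1	O2a1a1	2034000	G	A
SYN_O2a1a1a	O2a1a1a	2035000	T	C
SYN_O2a1a1a1	O2a1a1a1	2036000	A	G
SYN_O2a1a1a1a	O2a1a1a1a	2037000	C	T
SYN_O2a1a1a1a1	O2a1a1a1a1	2038000	G	A
SYN_O2a1b	O2a1b	2039000	T	C
SYN_O2a1b1	O2a1b1	2040000	A	G
SYN_O2a1b1a	O2a1b1a	2041000	C	T
SYN_O2a1b1a1	O2a1b1a1	2042000	G	A
SYN_O2a1b1a1a	O2a1b1a1a	2043000	T	C
SYN_O2a1b1a1a1	O2a1b1a1a1	2044000	A	G
SYN_O2a1b1a1a1a	O2a1b1a1a1a	2045000	C	T
SYN_O2a1b1a1a1a1	O2a1b1a1a1a1	2046000	G	A
SYN_O2a2	O2a2	2047000	T	C
SYN_O2a2a	O2a2a	2048000	A	G
SYN_O2a2a1	O2a2a1	2049000	C	T
SYN_O2a2a1a	O2a2a1a	2050000	G	A
SYN_O2a2b	O2a2b	2051000	T	C
SYN_O2a2b1	O2a2b1	2052000	A	G
SYN_O2a2b1a	O2a2b1a	2053000	C	T
SYN_O2a2b1a1	O2a2b1a1	2054000	G	A
SYN_O2a2b1a1a	O2a2b1a1a	2055000	T	C
SYN_O2a2b1a1a1	O2a2b1a1a1	2056000	A	G
SYN_O2a2b1a1a1a	O2a2b1a1a1a	2057000	C	T
SYN_O2a2b1a1a1a4	O2a2b1a1a1a4	2058000	G	A
SYN_O2a2b1a1a1a4a	O2a2b1a1a1a4a	2059000	T	C
SYN_O2a2b1a2	O2a2b1a2	2060000	A	G
SYN_O2a2b1a2a	O2a2b1a2a	2061000	C	T
SYN_O2a2b1a2a1	O2a2b1a2a1	2062000	G	A
SYN_O2a2b1a2a1a	O2a2b1a2a1a	2063000	T	C
SYN_O2a4	O2a4	2064000	A	G
M175	O	2950000	ATTCTC	A
M111	O1b1a1a1a1a1	2950100	AC	A
A15721	O1b1a1a1a1a1a1a1a	2950200	AG	A
M121	O2a1a1a1a1	2950300	AT	A
FGC12511	O2a1b1a	2950400	A	AT
M134	O2a2b1	2950500	AG	A
M117	O2a2b1a1	2950600	ACT	A
M133	O2a2b1a1a	2950700	A	AC
M333	O2a4	2950800	AGA	A
B384	O1a1	2950900	C	T
M1470	O1b1a	2951000	G	A
M188	O2a2a	2951100	A	G
CTS4658	O2a2b1a1a1a4a	2951200	C	A
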