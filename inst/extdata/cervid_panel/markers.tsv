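marker_id	group	mass_1	mass_2	annotation
P1	P1	1105	NA
A1150	A	1150	1166	alpha-2(I) 988-1000
A1180	A	1180	1196	alpha-2(I) 988-1000
B	B	1427	NA	alpha-2(I) 494-508
C1550	C	1550	NA	alpha-2(I) 512-529
C1580	C	1580	NA	alpha-2(I) 512-529
P2	P2	1648	NA
D	D	2131	NA	alpha-2(I) 803-826
F	F	2883	2899	alpha-1(I) 602-634
G3017	G	3017	3033	alpha-2(I) 767-799
G3043	G	3043	3059	alpha-2(I) 767-799
G3093	G	3093	NA	alpha-2(I) 767-799
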