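taxon	rank_group	group_report_label	P1	A1150	A1180	B	C1550	C1580	P2	D	F	G3017	G3043	G3093
Roe Deer	Cervidae	Bovid/Cervid	+	+	-	+	+	-	+	+	+	-	+	-
Red Deer	Cervidae	Bovid/Cervid	+	-	+	+	+	-	+	+	+	+	-	-
Fallow Deer	Cervidae	Bovid/Cervid	+	-	+	+	+	-	+	+	+	+	-	-
Caribou/Reindeer	Cervidae	Bovid/Cervid	+	-	+	+	-	+	+	+	+	-	-	+
White-Tailed Deer	Cervidae	Bovid/Cervid	+	-	+	+	-	d	+	+	+	-	d	-
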