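sample_id	P1	A1150	A1180	B	C1550	C1580	P2	D	F	G3017	G3043	G3093
DR-1454s	+	-	?	+	-	-	+	+	?	-	+	-
DR-1466s	+	-	+	+	-	?	+	+	?	-	+	-
DR-1588s	+	-	+	+	-	+	+	+	+	-	+	-
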