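sample_id	artefact_type	original_bag	forced_bag	eraser	destructive	dna	burnt	tooth_pendant	is_control
DR-21s	Bevelled conical point	Bear	N/T	Probable bear	Bear	U. americanus	FALSE	FALSE	FALSE
DR-491s	Bevelled conical point	Probable bear	Probable bear	Probable bear	Bear	N/T	FALSE	FALSE	FALSE
DR-894s	Bevelled conical point	X	N/T	Human	Human	H. sapiens	FALSE	FALSE	FALSE
DR-1044s	Pendant	N/T	N/T	X	N/T	N/T	FALSE	TRUE	FALSE
DR-1130s	Harpoon	X	X	Carnivora (possible Cat/Bear)	Bear	N/T	FALSE	FALSE	FALSE
DR-1454s	Point	Probable Bovid/Cervid	Probable Bovid/Cervid	Probable Bovid/Cervid	White-tailed deer	N/T	FALSE	FALSE	FALSE
DR-1466s	Point or awl	Probable Bovid/Cervid	Probable Bovid/Cervid	Probable Bovid/Cervid	White-tailed deer	N/T	FALSE	FALSE	FALSE
DR-1588s	Point or awl	X	Probable Bovid/Cervid	Probable Bovid/Cervid	White-tailed deer	N/T	FALSE	FALSE	FALSE
DR-1662s	Bevelled conical point	Probable bear	N/T	Bear	Bear	U. americanus	FALSE	FALSE	FALSE
DR-1797s	Harpoon	X	Human	Human	N/T	H. sapiens	FALSE	FALSE	FALSE
DR-1926s	Bevelled conical point	X	Carnivora	Carnivora	Carnivora	N/T	FALSE	FALSE	FALSE
DR-2271s	Harpoon	X	N/T	X	N/T	N/T	TRUE	FALSE	FALSE
DR-5448s	Bevelled conical point	X	N/T	X	N/T	N/T	TRUE	FALSE	FALSE
MC-398s	Point	X	Human	X	Human	Fail	FALSE	FALSE	FALSE
BgFo-18	Bevelled conical point	X	X	Carnivora	Bear	N/T	FALSE	FALSE	FALSE
Control bag	N/A	X	X	N/A	N/A	N/T	FALSE	FALSE	TRUE
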