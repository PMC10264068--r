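nuclease_name	source_organism	isotype	anticodon	cleavage_bond	motif	modification_dependent	citation_note
VapC-LT2	Shigella flexneri / Salmonella enterica	fMet	cat	anticodon	-	0	cuts initiator tRNA-fMet within the anticodon
PrrC	Escherichia coli	Lys	ttt	anticodon	-	0	activated on sensing phage T4 Stp; coliphages carry tRNA ligases (rnl1/rnl2) that repair the cleaved tRNA-Lys
Colicin D	Escherichia coli	Arg	*	5	-	0	targets all arginine isoacceptors; cut on the 3' side of the anticodon loop, exact bond not stated in the source text (placed at loop bond 5)
Colicin E5	Escherichia coli	Tyr	gta	anticodon	-	1	cleavage depends on the modified wobble position (queuosine)
Colicin E5	Escherichia coli	His	gtg	anticodon	-	1	cleavage depends on the modified wobble position (queuosine)
Colicin E5	Escherichia coli	Asn	gtt	anticodon	-	1	cleavage depends on the modified wobble position (queuosine)
Colicin E5	Escherichia coli	Asp	gtc	anticodon	-	1	cleavage depends on the modified wobble position (queuosine)
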