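nuclease_name	source_organism	isotype	anticodon	cleavage_bond	motif	modification_dependent	citation_note
VapC	Mycobacterium smegmatis / M. tuberculosis	Ser	gga	anticodon	GA	0	cuts serine isoacceptors at the GA dinucleotide within the anticodon
VapC	Mycobacterium smegmatis / M. tuberculosis	Ser	tga	anticodon	GA	0	cuts serine isoacceptors at the GA dinucleotide within the anticodon
VapC	Mycobacterium smegmatis / M. tuberculosis	Ser	cga	anticodon	GA	0	cuts serine isoacceptors at the GA dinucleotide within the anticodon
VapC	Mycobacterium smegmatis / M. tuberculosis	Ser	aga	anticodon	GA	0	cuts serine isoacceptors at the GA dinucleotide within the anticodon
RelE	Mycobacterium smegmatis / M. tuberculosis	Sup	cta	anticodon	-	0	stop-codon-reading anticodon listed among RelE targets
RelE	Mycobacterium smegmatis / M. tuberculosis	Leu	tta	anticodon	-	0	listed among RelE targets
RelE	Mycobacterium smegmatis / M. tuberculosis	Gln	cga	anticodon	-	0	transcribed verbatim from the source target list; note that anticodon cga would not decode a Gln codon - verify before use
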