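snp_id	population	maf	ref_aa	alt_aa	protein_position	functional_annotation	conservation_pct
rs148464069	African ancestry (US)	0.0004	K	E	216	Hsp70 interaction	92.1
rs574806930	African (Gambia)	0.0004	M	V	215	Packing interaction	93.4
rs114225550	African; American	0.0124	S	G	233	unknown	91.5
COSM753616	pancreatic and lung cancer	0	E	K	219	Hsp70 interaction	93.4
COSM172723	Large Intestine cancer	0	N	I	229	Hsp70 interaction	86.1
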