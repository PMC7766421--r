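protein_position	annotation	priority
215	Packing interaction	2
216	Hsp70 interaction	1
219	Hsp70 interaction	1
229	Hsp70 interaction	1
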