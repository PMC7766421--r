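name	start_codon	end_codon
UBQ_like	10	86
BAG	220	300
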