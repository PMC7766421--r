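region	n_nsSNP	nonsyn_sites	n_sSNP	syn_sites
full_length	25	790.17	12	244.83
UBQ_like	3	178.17	3	52.83
BAG	6	192	1	51
domain_total	9	370.17	4	103.83
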