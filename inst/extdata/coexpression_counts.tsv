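fate	marker	double_positive	marker_only
Sertoli	AMH	1106	10165
Granulosa	FOXL2	205	2850
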