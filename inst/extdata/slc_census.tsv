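group	sex	n_cells
early	XY	289
early	XX	171
late	XY	312
late	XX	580
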