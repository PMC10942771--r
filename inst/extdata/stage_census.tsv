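stage	n_cells
E10.5	14962
E11.5	16670
E12.5	20285
E13.5	25794
E16.5	16994
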