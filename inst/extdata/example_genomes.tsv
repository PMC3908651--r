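genome_id	chromosome_id	genes
ga	chr1	100 101 102 103 104 1 2 3 4 105 106 107 108 109
gb	chr1	200 201 202 203 204 3 1 4 2 205 206 207 208 209
gc	chr1	300 301 302 303 304 2 4 3 1 305 306 307 308 309
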