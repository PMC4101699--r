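PLANTED_SET	synthetic demo set	G00001	G00002	G00003	G00004	G00005
RANDOM_SET	synthetic demo set	G00010	G00011	G00012	G00013	G00014	G00015	G00016	G00017
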