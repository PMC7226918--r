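compartment	inhibitory_score	sensitivity_score
soil	63.41	20.25
stem	47.62	47.99
leaf	44.21	56.26
flower	32.27	46.39
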