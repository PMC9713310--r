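# Default rendering palette for mycorrhizal maps; override any subset.
EMPTY: '#FFFFFF'
HYPHA: '#1F4FFF'
ARBUSCULE: '#E02020'
VESICLE: '#18A018'
SPORE: '#808080'
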