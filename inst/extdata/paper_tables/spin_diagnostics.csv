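oxidation_state,multiplicity,stage,observed_s2
II,5,pre-annihilation,6.0079
II,5,post-annihilation,6.0000
III,6,pre-annihilation,8.7625
III,6,post-annihilation,8.7501
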