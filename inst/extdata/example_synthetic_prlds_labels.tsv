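example_pos_001	positive
example_pos_002	positive
example_pos_003	positive
example_pos_004	positive
example_neg_001	negative
example_neg_002	negative
example_neg_003	negative
example_neg_004	negative
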