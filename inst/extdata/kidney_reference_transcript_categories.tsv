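category	count
Not detected	3764
Low	5465
Medium	5452
High	5481
total	20162
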