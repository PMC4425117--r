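query	identical	unique_control	unique_autism
1	19959	834	161
2	41035	853	195
3	14451	356	387
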