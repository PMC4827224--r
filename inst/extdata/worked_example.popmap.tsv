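s1	P1
s2	P1
s3	P2
s4	P2
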