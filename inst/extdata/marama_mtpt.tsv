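fragment	length
M	9798
f2	859
f3	342
f4	273
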