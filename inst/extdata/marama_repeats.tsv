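label	length	kind
H	5212	direct
I	2351	inverted
J	3908	direct
O	4926	direct
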