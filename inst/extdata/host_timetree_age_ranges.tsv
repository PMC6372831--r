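node	lo	hi
serpentes	72	90
psittaciformes	30	60
mus	6	7
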