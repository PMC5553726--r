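gene	variant	nnsplice	netgene2	hsf	asseda
CRB1	p.(Ile205Aspfs*13)	negative	positive	positive	positive
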