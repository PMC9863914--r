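canonical	name
ibrutinib	ibrutinib
ibrutinib	Imbruvica
ibrutinib	PCI-32765
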