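from_protein	to_protein	offset
heIF4E1a	XeIF4E1b	0
XeIF4E1b	heIF4E1a	0
XeIF4E1a	heIF4E1a	4
heIF4E1a	XeIF4E1a	-4
XeIF4E1a	XeIF4E1b	4
XeIF4E1b	XeIF4E1a	-4
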