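chrS	786975	787200	.	0	.
chrS	1074101	1074828	.	0	.
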