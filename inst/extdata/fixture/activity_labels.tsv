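gene_id	cell_type	status
simg0001	H1	inactive
simg0002	H1	active
simg0003	H1	inactive
simg0004	H1	active
simg0005	H1	inactive
simg0006	H1	active
simg0001	K562	inactive
simg0002	K562	inactive
simg0003	K562	inactive
simg0004	K562	active
simg0005	K562	inactive
simg0006	K562	inactive
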