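gene_id	tissue01	tissue02	tissue03	tissue04	tissue05	tissue06
simg0001	0	2.7417	1.0845	0	0	0
simg0002	0	0	0	0.7224	0.8818	0
simg0003	0	0	0	0	0	0
simg0004	0	0	2.0849	0	6.1371	0
simg0005	2.9678	2.1703	0.835	0	0.4094	0.957
simg0006	0	0	0	0	0	4.8628
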