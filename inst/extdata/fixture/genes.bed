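chrS	157759	158197	simg0001	0	+	157759	158197	0	2	82,84,	0,354,
chrS	307242	307334	simg0002	0	+	307242	307334	0	1	92,	0,
chrS	544061	544601	simg0003	0	+	544061	544601	0	2	165,131,	0,409,
chrS	786609	787389	simg0004	0	+	786609	787389	0	2	114,112,	0,668,
chrS	951909	952560	simg0005	0	+	951909	952560	0	2	142,156,	0,495,
chrS	1074101	1074721	simg0006	0	+	1074101	1074721	0	2	84,130,	0,490,
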