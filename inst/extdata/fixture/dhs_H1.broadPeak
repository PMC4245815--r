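chrS	173227	173912	.	0	.
chrS	254232	254795	.	0	.
chrS	258663	258876	.	0	.
chrS	260491	260963	.	0	.
chrS	303778	304175	.	0	.
chrS	304354	304643	.	0	.
chrS	311681	312091	.	0	.
chrS	455539	455879	.	0	.
chrS	462633	463395	.	0	.
chrS	467114	467562	.	0	.
chrS	490881	491335	.	0	.
chrS	538553	538869	.	0	.
chrS	580247	580954	.	0	.
chrS	697917	698179	.	0	.
chrS	713830	714302	.	0	.
chrS	757497	757927	.	0	.
chrS	787547	788012	.	0	.
chrS	819037	819811	.	0	.
chrS	829069	829439	.	0	.
chrS	845457	846222	.	0	.
chrS	965818	966374	.	0	.
chrS	982114	982601	.	0	.
chrS	1052672	1053423	.	0	.
chrS	1071672	1071942	.	0	.
chrS	1074102	1074710	.	0	.
chrS	1087517	1087733	.	0	.
chrS	1095560	1095827	.	0	.
chrS	1100415	1101093	.	0	.
chrS	1114997	1115461	.	0	.
chrS	1115774	1116213	.	0	.
chrS	1140404	1140920	.	0	.
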