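chr2	66260932	66300000	Scn1a	0	-	66260932	66300000	0	27	1200,183,228,114,162,130,64,273,174,246,96,270,168,105,285,159,138,92,273,216,273,92,186,274,90,141,237	0,2702,3786,4880,6127,8339,10276,12791,13965,15005,16384,18530,19544,21214,22220,23371,24663,26851,27687,29462,30579,31718,32943,35179,36197,37789,38831
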