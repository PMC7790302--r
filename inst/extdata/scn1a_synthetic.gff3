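##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-24
chr2	rtracklayer	gene	66260933	66300000	.	-	.	ID=Scn1a;Name=Scn1a;
chr2	rtracklayer	mRNA	66260933	66300000	.	-	.	ID=Scn1a.t1;Parent=Scn1a
chr2	rtracklayer	exon	66260933	66262132	.	-	.	ID=Scn1a.t1.ex26;Name=ex26;Parent=Scn1a.t1
chr2	rtracklayer	exon	66263635	66263817	.	-	.	ID=Scn1a.t1.ex25;Name=ex25;Parent=Scn1a.t1
chr2	rtracklayer	exon	66264719	66264946	.	-	.	ID=Scn1a.t1.ex24;Name=ex24;Parent=Scn1a.t1
chr2	rtracklayer	exon	66265813	66265926	.	-	.	ID=Scn1a.t1.ex23;Name=ex23;Parent=Scn1a.t1
chr2	rtracklayer	exon	66267060	66267221	.	-	.	ID=Scn1a.t1.ex22;Name=ex22;Parent=Scn1a.t1
chr2	rtracklayer	exon	66269272	66269401	.	-	.	ID=Scn1a.t1.ex21;Name=ex21;Parent=Scn1a.t1
chr2	rtracklayer	exon	66271209	66271272	.	-	.	ID=Scn1a.t1.ex20N;Name=ex20N;Parent=Scn1a.t1
chr2	rtracklayer	exon	66273724	66273996	.	-	.	ID=Scn1a.t1.ex20;Name=ex20;Parent=Scn1a.t1
chr2	rtracklayer	exon	66274898	66275071	.	-	.	ID=Scn1a.t1.ex19;Name=ex19;Parent=Scn1a.t1
chr2	rtracklayer	exon	66275938	66276183	.	-	.	ID=Scn1a.t1.ex18;Name=ex18;Parent=Scn1a.t1
chr2	rtracklayer	exon	66277317	66277412	.	-	.	ID=Scn1a.t1.ex17;Name=ex17;Parent=Scn1a.t1
chr2	rtracklayer	exon	66279463	66279732	.	-	.	ID=Scn1a.t1.ex16;Name=ex16;Parent=Scn1a.t1
chr2	rtracklayer	exon	66280477	66280644	.	-	.	ID=Scn1a.t1.ex15;Name=ex15;Parent=Scn1a.t1
chr2	rtracklayer	exon	66282147	66282251	.	-	.	ID=Scn1a.t1.ex14;Name=ex14;Parent=Scn1a.t1
chr2	rtracklayer	exon	66283153	66283437	.	-	.	ID=Scn1a.t1.ex13;Name=ex13;Parent=Scn1a.t1
chr2	rtracklayer	exon	66284304	66284462	.	-	.	ID=Scn1a.t1.ex12;Name=ex12;Parent=Scn1a.t1
chr2	rtracklayer	exon	66285596	66285733	.	-	.	ID=Scn1a.t1.ex11;Name=ex11;Parent=Scn1a.t1
chr2	rtracklayer	exon	66287784	66287875	.	-	.	ID=Scn1a.t1.ex10;Name=ex10;Parent=Scn1a.t1
chr2	rtracklayer	exon	66288620	66288892	.	-	.	ID=Scn1a.t1.ex09;Name=ex09;Parent=Scn1a.t1
chr2	rtracklayer	exon	66290395	66290610	.	-	.	ID=Scn1a.t1.ex08;Name=ex08;Parent=Scn1a.t1
chr2	rtracklayer	exon	66291512	66291784	.	-	.	ID=Scn1a.t1.ex07;Name=ex07;Parent=Scn1a.t1
chr2	rtracklayer	exon	66292651	66292742	.	-	.	ID=Scn1a.t1.ex06;Name=ex06;Parent=Scn1a.t1
chr2	rtracklayer	exon	66293876	66294061	.	-	.	ID=Scn1a.t1.ex05;Name=ex05;Parent=Scn1a.t1
chr2	rtracklayer	exon	66296112	66296385	.	-	.	ID=Scn1a.t1.ex04;Name=ex04;Parent=Scn1a.t1
chr2	rtracklayer	exon	66297130	66297219	.	-	.	ID=Scn1a.t1.ex03;Name=ex03;Parent=Scn1a.t1
chr2	rtracklayer	exon	66298722	66298862	.	-	.	ID=Scn1a.t1.ex02;Name=ex02;Parent=Scn1a.t1
chr2	rtracklayer	exon	66299764	66300000	.	-	.	ID=Scn1a.t1.ex01;Name=ex01;Parent=Scn1a.t1
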