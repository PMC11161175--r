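chrom	pos	A	C	G	T
chr1	2678	10	0	0	4
chr1	4666	7	0	0	7
chr1	11786	0	8	0	5
chr1	12357	11	0	7	0
chr1	14135	7	0	0	8
chr1	16849	0	0	9	8
chr1	19893	10	0	0	16
chr1	21588	9	0	8	0
chr1	24338	13	7	0	0
chr1	25111	9	0	13	0
chr1	28660	0	8	8	0
chr1	35311	0	6	10	0
chr1	37243	3	0	0	5
chr1	40336	11	12	0	0
chr1	40538	0	7	12	0
chr1	41194	0	0	6	9
chr1	42428	0	0	14	13
chr1	47925	0	8	0	5
chr1	48959	0	14	0	7
chr1	49097	0	11	5	0
chr1	51603	0	0	4	3
chr1	53444	12	0	12	0
chr1	58720	0	0	13	9
chr1	63254	15	13	0	0
chr1	65070	0	11	9	0
chr1	66478	0	15	0	8
chr1	66754	0	9	6	0
chr1	67814	0	0	5	12
chr1	68069	6	0	0	9
chr1	69336	12	0	4	0
chr1	76007	4	10	0	0
chr1	76477	0	10	0	13
chr1	76820	0	6	0	13
chr1	77222	11	9	0	0
chr1	77997	7	0	10	0
chr1	79998	0	15	7	0
chr1	81366	0	9	7	0
chr1	82254	0	14	12	0
chr1	86931	0	10	0	7
chr1	87619	9	0	8	0
chr1	91813	13	0	0	4
chr1	95270	0	7	0	6
chr1	95446	6	0	0	11
chr1	95523	11	0	11	0
chr1	95709	7	0	0	12
chr1	96416	0	0	11	6
chr1	98708	5	0	8	0
chr1	99539	9	0	0	7
chr1	103726	13	0	0	9
chr1	105943	0	0	7	6
chr1	110607	2	8	0	0
chr1	119913	13	0	0	10
chr1	125822	7	14	0	0
chr1	128457	9	0	7	0
chr1	129412	15	12	0	0
chr1	130174	7	0	15	0
chr1	130334	8	0	9	0
chr1	132159	8	0	7	0
chr1	132401	6	1	10	0
chr1	133693	0	15	5	0
chr1	137404	9	9	0	0
chr1	138546	7	7	0	0
chr1	142224	7	0	0	10
chr1	142502	0	8	0	7
chr1	143523	5	0	7	0
chr1	144742	11	0	14	0
chr1	146462	12	0	9	0
chr1	151417	0	10	10	0
chr1	153262	14	12	0	0
chr1	153968	0	9	9	0
chr1	155464	0	6	6	0
chr1	155489	0	11	6	0
chr1	155782	0	10	6	0
chr1	156586	9	9	0	0
chr1	157871	7	0	12	0
chr1	158847	0	0	10	11
chr1	159461	11	0	0	11
chr1	164189	13	0	8	0
chr1	165474	7	5	0	0
chr1	167888	17	0	0	9
chr1	172241	0	7	0	11
chr1	172867	5	0	0	9
chr1	173938	0	9	0	4
chr1	175064	6	13	0	0
chr1	175253	0	6	11	0
chr1	178439	0	8	6	1
chr1	179677	0	6	9	0
chr1	181641	0	0	8	14
chr1	182575	12	0	14	0
chr1	186941	0	0	5	11
chr1	188935	6	0	0	8
chr1	192123	8	9	0	0
chr1	198381	9	0	0	11
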