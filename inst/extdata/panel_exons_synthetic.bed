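# Synthetic BED-like coordinate stub for the 14 panel genes (hg19-style
# labels). Intervals are approximate gene bodies used only to draw
# plausible positions for simulated background variants; they are NOT
# curated exon annotations.
chr12	8975068	9039597	A2ML1
chr7	140419127	140624564	BRAF
chr11	119076986	119178859	CBL
chr11	532242	535567	HRAS
chr12	25358180	25403854	KRAS
chr15	66679155	66783882	MAP2K1
chr19	4090319	4124126	MAP2K2
chr1	115247085	115259515	NRAS
chr12	112856155	112947717	PTPN11
chr3	12625100	12705700	RAF1
chr1	155867512	155881195	RIT1
chr10	112723966	112773925	SHOC2
chr2	39208690	39347604	SOS1
chr15	38545525	38649450	SPRED1
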