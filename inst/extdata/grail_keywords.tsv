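keyword	genes
Synthase	ST3GAL3;ELP2
Reductase	FASN;ENTPD1;ADK
Mitochondrial	CASP2;PECR;CRADD;RABL6;TECR;ADK;FASN
Apoptosis	RABL6;ELP2;FASN;ENTPD1;HIST3H3;MED23;ADK
Methyltransferase	HIST3H3
Elegans	CASP2;TRMT1;TUSC3;SCAPER;RABL6;ASCC3;TRAPPC9;ADK;PRSS12;CRADD;EEF1B2
Complex	MED23;EEF1B2;CRADD;HIST3H3;CASP2;SCAPER;TRAPPC9;TECR;ASCC3;MAN1B1;RALGDS;TTI2
Death	TRAPPC9;FASN;ENTPD1;NDST1
Genome	TRAPPC9;ELP2;TECR;RABL6;TRMT1;COQ5;EEF1B2;PRSS12;TUSC3;MED23
Histone	CC2D1A;MED23
Enzyme	ADK;TUSC3;ST3GAL3;PECR;PRSS12;MAN1B1;FASN;ENTPD1;CASP2;TECR;SCAPER;HIST3H3
Trna	ELP2;TUSC3;TECR
Adenosine	NDST1
Elongation	ELP2;PECR;MED23;RALGDS;TUSC3
Fatty	PECR;ADK;CASP2
Saccharomyces	ELP2;ASCC3;MAN1B1;COQ5;EEF1B2;TECR;ADK;NDST1;MED23
Cerevisiae	TRMT1;ASCC3;MAN1B1;COQ5;EEF1B2;TECR;ADK;NDST1;MED23
Yeast	COQ5;EEF1B2;TRMT1;ASCC3;RABL6;TECR;MAN1B1;MED23;RALGDS;SCAPER;HIST3H3;TRAPPC9;NDST1
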