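size	fidelity	members	seed
10	1	AATG,ATCC,CCAA,CGGC,GCTT,GTCA,GTGC,TACG,TAGA,TCGT	110
20	1	AACT,AATG,ACAA,ACTC,AGAC,ATAG,ATCC,ATTA,CCGT,CTGA,GCAC,GCCG,GCTT,GGCA,GGTG,TACG,TCCT,TGGG,TTCA,TTTG	120
30	0.987587601707833	AACT,AATG,ACAT,ACGA,ACTC,AGCC,AGGG,ATCG,CACC,CAGG,CCAC,CGCA,CGGT,CTCT,CTTG,GACG,GATA,GCAG,GCCA,GCTT,GGGA,GTAT,GTCC,TAAC,TACT,TCGG,TCTA,TGAA,TTAG,TTTT	130
40	0.929231466063467	AATA,AATG,ACAG,ACTT,AGAT,AGGA,AGTT,ATAC,ATGG,ATTC,CACC,CAGG,CCCA,CCCG,CGAC,CGAG,CGCT,CGTA,CGTC,CTGA,CTTT,GAAA,GATA,GCAA,GCCT,GCGG,GCTC,GCTT,GGGA,GGGT,GTAG,GTCC,GTGT,TAAC,TCGT,TCTA,TGCC,TTAT,TTCA,TTTG	140
50	0.827300492764955	AAAT,AAGA,AATG,ACCA,ACTA,ACTG,AGAG,AGCC,AGGT,AGTC,AGTT,ATAA,ATAC,CAAG,CACC,CAGC,CCAT,CCCG,CCGC,CCGT,CGAT,CGTA,CTGA,CTGG,GAAA,GAAC,GAAT,GAGG,GCAA,GCCC,GCTT,GGAG,GGCA,GTAG,GTCG,GTGT,TAAC,TACA,TAGG,TATC,TATT,TCAA,TCCC,TCCT,TCGC,TGCT,TGTG,TTCA,TTCG,TTTA	150
60	0.697820577741946	AACG,AATA,AATG,ACAA,ACCC,ACCT,ACTG,AGAG,AGTG,AGTT,ATCG,ATGG,ATGT,CAAG,CAGA,CATA,CCAG,CCCG,CCGT,CCTA,CGGC,CGTG,CTCC,GAAC,GAAT,GAGG,GAGT,GATA,GATG,GCGG,GCTT,GGCA,GGGC,GGTC,GGTG,GTAG,GTAT,GTCA,GTCT,GTGA,GTGC,GTTG,TAAT,TAGC,TCAG,TCCC,TCCT,TCGC,TCGT,TCTT,TGCT,TGGG,TGTA,TTAG,TTAT,TTCA,TTCG,TTGA,TTTC,TTTT	160
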