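# Synthetic netropsin binding-constant table (1/uM), one 4MER<TAB>constant per line.
# AT-content-graded stand-in: log K linear in the number of A/T bases,
# 0.5 /uM (all-GC) to 150 /uM (all-AT). Not measured data; replace with a
# laboratory table for real analyses.
AAAA	150
AAAC	36.04
AAAG	36.04
AAAT	150
AACA	36.04
AACC	8.66
AACG	8.66
AACT	36.04
AAGA	36.04
AAGC	8.66
AAGG	8.66
AAGT	36.04
AATA	150
AATC	36.04
AATG	36.04
AATT	150
ACAA	36.04
ACAC	8.66
ACAG	8.66
ACAT	36.04
ACCA	8.66
ACCC	2.081
ACCG	2.081
ACCT	8.66
ACGA	8.66
ACGC	2.081
ACGG	2.081
ACGT	8.66
ACTA	36.04
ACTC	8.66
ACTG	8.66
ACTT	36.04
AGAA	36.04
AGAC	8.66
AGAG	8.66
AGAT	36.04
AGCA	8.66
AGCC	2.081
AGCG	2.081
AGCT	8.66
AGGA	8.66
AGGC	2.081
AGGG	2.081
AGGT	8.66
AGTA	36.04
AGTC	8.66
AGTG	8.66
AGTT	36.04
ATAA	150
ATAC	36.04
ATAG	36.04
ATAT	150
ATCA	36.04
ATCC	8.66
ATCG	8.66
ATCT	36.04
ATGA	36.04
ATGC	8.66
ATGG	8.66
ATGT	36.04
ATTA	150
ATTC	36.04
ATTG	36.04
ATTT	150
CAAA	36.04
CAAC	8.66
CAAG	8.66
CAAT	36.04
CACA	8.66
CACC	2.081
CACG	2.081
CACT	8.66
CAGA	8.66
CAGC	2.081
CAGG	2.081
CAGT	8.66
CATA	36.04
CATC	8.66
CATG	8.66
CATT	36.04
CCAA	8.66
CCAC	2.081
CCAG	2.081
CCAT	8.66
CCCA	2.081
CCCC	0.5
CCCG	0.5
CCCT	2.081
CCGA	2.081
CCGC	0.5
CCGG	0.5
CCGT	2.081
CCTA	8.66
CCTC	2.081
CCTG	2.081
CCTT	8.66
CGAA	8.66
CGAC	2.081
CGAG	2.081
CGAT	8.66
CGCA	2.081
CGCC	0.5
CGCG	0.5
CGCT	2.081
CGGA	2.081
CGGC	0.5
CGGG	0.5
CGGT	2.081
CGTA	8.66
CGTC	2.081
CGTG	2.081
CGTT	8.66
CTAA	36.04
CTAC	8.66
CTAG	8.66
CTAT	36.04
CTCA	8.66
CTCC	2.081
CTCG	2.081
CTCT	8.66
CTGA	8.66
CTGC	2.081
CTGG	2.081
CTGT	8.66
CTTA	36.04
CTTC	8.66
CTTG	8.66
CTTT	36.04
GAAA	36.04
GAAC	8.66
GAAG	8.66
GAAT	36.04
GACA	8.66
GACC	2.081
GACG	2.081
GACT	8.66
GAGA	8.66
GAGC	2.081
GAGG	2.081
GAGT	8.66
GATA	36.04
GATC	8.66
GATG	8.66
GATT	36.04
GCAA	8.66
GCAC	2.081
GCAG	2.081
GCAT	8.66
GCCA	2.081
GCCC	0.5
GCCG	0.5
GCCT	2.081
GCGA	2.081
GCGC	0.5
GCGG	0.5
GCGT	2.081
GCTA	8.66
GCTC	2.081
GCTG	2.081
GCTT	8.66
GGAA	8.66
GGAC	2.081
GGAG	2.081
GGAT	8.66
GGCA	2.081
GGCC	0.5
GGCG	0.5
GGCT	2.081
GGGA	2.081
GGGC	0.5
GGGG	0.5
GGGT	2.081
GGTA	8.66
GGTC	2.081
GGTG	2.081
GGTT	8.66
GTAA	36.04
GTAC	8.66
GTAG	8.66
GTAT	36.04
GTCA	8.66
GTCC	2.081
GTCG	2.081
GTCT	8.66
GTGA	8.66
GTGC	2.081
GTGG	2.081
GTGT	8.66
GTTA	36.04
GTTC	8.66
GTTG	8.66
GTTT	36.04
TAAA	150
TAAC	36.04
TAAG	36.04
TAAT	150
TACA	36.04
TACC	8.66
TACG	8.66
TACT	36.04
TAGA	36.04
TAGC	8.66
TAGG	8.66
TAGT	36.04
TATA	150
TATC	36.04
TATG	36.04
TATT	150
TCAA	36.04
TCAC	8.66
TCAG	8.66
TCAT	36.04
TCCA	8.66
TCCC	2.081
TCCG	2.081
TCCT	8.66
TCGA	8.66
TCGC	2.081
TCGG	2.081
TCGT	8.66
TCTA	36.04
TCTC	8.66
TCTG	8.66
TCTT	36.04
TGAA	36.04
TGAC	8.66
TGAG	8.66
TGAT	36.04
TGCA	8.66
TGCC	2.081
TGCG	2.081
TGCT	8.66
TGGA	8.66
TGGC	2.081
TGGG	2.081
TGGT	8.66
TGTA	36.04
TGTC	8.66
TGTG	8.66
TGTT	36.04
TTAA	150
TTAC	36.04
TTAG	36.04
TTAT	150
TTCA	36.04
TTCC	8.66
TTCG	8.66
TTCT	36.04
TTGA	36.04
TTGC	8.66
TTGG	8.66
TTGT	36.04
TTTA	150
TTTC	36.04
TTTG	36.04
TTTT	150
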