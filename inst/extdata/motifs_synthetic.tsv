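name	iupac
ELEM001	TCTAMAC
ELEM002	GTGTCGC
ELEM003	GAGCCATG
ELEM004	ASCGCTTG
ELEM005	TGKTTC
ELEM006	GTAAACTAK
ELEM007	GGWGGTG
ELEM008	TGAAGTC
ELEM009	KCTTGAGTC
ELEM010	RTGTCTT
ELEM011	TGCTCTGA
ELEM012	CGCBTGT
ELEM013	TACATCAT
ELEM014	TAGCGCG
ELEM015	TTGTAAA
ELEM016	TTGACHGGC
ELEM017	GGAGTAGG
ELEM018	TCCCAGGAC
ELEM019	CRCAGC
ELEM020	GGGGACG
ELEM021	CCTGBAACT
ELEM022	CTCGTCGAM
ELEM023	GTAGCAAWA
ELEM024	ATYGAGT
ELEM025	GTGAGAG
ELEM026	STGTTAGG
ELEM027	TGTGATTA
ELEM028	TCGATTTC
ELEM029	CCGCCGD
ELEM030	GGGCCA
ELEM031	ACTAAAACCG
ELEM032	TTAGGAAAST
ELEM033	CAAWGCC
ELEM034	TCCHTG
ELEM035	GCGACCAR
ELEM036	ASACCC
ELEM037	CCCGTCTCT
ELEM038	TCGMCAA
ELEM039	ACHTATA
ELEM040	DTCTGGGCT
ELEM041	CCBTAGA
ELEM042	ATAACAAGA
ELEM043	GACAGS
ELEM044	CGGGCA
ELEM045	TATAAAR
ELEM046	CCGCSCC
ELEM047	VTAGGC
ELEM048	TTCTGTTT
ELEM049	GGTACAAT
ELEM050	TGAKTGA
ELEM051	ACAGGTCATC
ELEM052	TCVATCGGC
ELEM053	AATGGCTA
ELEM054	GAGCCTC
ELEM055	CCGAGWGC
ELEM056	AAAATA
ELEM057	GGTCSCAAT
ELEM058	ATAGTGAAAG
ELEM059	ATCCCTGG
ELEM060	TTTTGGA
ELEM061	CGAAAAA
ELEM062	CGTGGCGA
ELEM063	GGCCGCC
ELEM064	ATCGCAGCC
ELEM065	GGGGGGGACG
ELEM066	AACCTGGA
ELEM067	GGTCTGTG
ELEM068	GAGCGYC
ELEM069	TCTTGGB
ELEM070	CTYCAA
ELEM071	AACGATCCM
ELEM072	CAGGGAYA
ELEM073	CCAAGTYT
ELEM074	GCCACWT
ELEM075	GATDTACTCG
ELEM076	CTATTAG
ELEM077	CGTTCGTTT
ELEM078	CCAGGAG
ELEM079	ACGGCA
ELEM080	TAKCCTCGC
ELEM081	CCGAATA
ELEM082	TGCTCCCT
ELEM083	KAATCTAC
ELEM084	RGAGTCGCCA
ELEM085	AGTCACAT
ELEM086	TCCTAGAA
ELEM087	AGGAACAT
ELEM088	TACATACG
ELEM089	TTTGTGT
ELEM090	TCCGCGTAG
ELEM091	AACGCACA
ELEM092	TCGTTTG
ELEM093	GAGGGAC
ELEM094	AGCTACAS
ELEM095	CCGGTADTT
ELEM096	CTCTGA
ELEM097	GAAACCACA
ELEM098	TTTCTR
ELEM099	GTATTC
ELEM100	GCCGCCG
ELEM101	TGTTGTCCA
ELEM102	ACAGCCATTT
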